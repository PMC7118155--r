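#' Grey-level co-occurrence matrix
#'
#' Counts ordered pairs of grey levels at a fixed pixel offset. Entry
#' `(i, j)` (0-based grey values) is the number of pixel positions
#' `(m, n)` with `I(m, n) = i` and `I(m + k, n + l) = j`, where
#' `offset = c(k, l)` is expressed in (row, column) steps. Positions whose
#' offset partner falls outside the image are skipped (no wraparound or
#' padding), so for offset `(0, 1)` on an `M x N` image the total pair
#' count is `M * (N - 1)`. The matrix is directional (not symmetrized) by
#' default; `symmetric = TRUE` adds the transpose, counting each pair in
#' both orders.
#'
#' The default offset `(0, 1)` compares horizontally adjacent pixels,
#' which captures the alternating intensity variation of speckle along a
#' B-mode scan line. Construction is a single vectorized pass, O(M N).
#'
#' @param image A [grey_image()].
#' @param offset Integer pair `c(k, l)`: row and column displacement.
#'   Must not be `c(0, 0)`.
#' @param symmetric Count each pair in both orders (default `FALSE`).
#'
#' @return An object of class `glcm`: the `L x L` count matrix with
#'   attributes `offset`, `levels` and `total_pairs`.
#' @export
#' @examples
#' img <- grey_image(matrix(c(0, 1, 1, 0), 2, 2), levels = 2)
#' compute_glcm(img, c(0, 1))
compute_glcm <- function(image, offset = c(0L, 1L), symmetric = FALSE) {
  stopifnot(inherits(image, "grey_image"))
  offset <- as.integer(offset)
  if (length(offset) != 2L || anyNA(offset)) {
    stop("`offset` must be an integer pair c(k, l)", call. = FALSE)
  }
  k <- offset[1]; l <- offset[2]
  if (k == 0L && l == 0L) stop("offset c(0, 0) is not a valid displacement", call. = FALSE)
  M <- nrow(image); N <- ncol(image); L <- n_levels(image)
  r_from <- max(1L, 1L - k); r_to <- min(M, M - k)
  c_from <- max(1L, 1L - l); c_to <- min(N, N - l)
  if (r_from > r_to || c_from > c_to) {
    stop(sprintf("image (%d x %d) is too small for offset (%d, %d)", M, N, k, l),
      call. = FALSE)
  }
  rows <- seq.int(r_from, r_to)
  cols <- seq.int(c_from, c_to)
  px <- unclass(image)
  i <- px[rows, cols, drop = FALSE]
  j <- px[rows + k, cols + l, drop = FALSE]
  counts <- tabulate(as.vector(i) * L + as.vector(j) + 1L, nbins = L * L)
  chi <- matrix(counts, nrow = L, ncol = L, byrow = TRUE)
  if (symmetric) chi <- chi + t(chi)
  dimnames(chi) <- list(0:(L - 1L), 0:(L - 1L))
  structure(chi,
    offset = c(k, l), levels = L, total_pairs = sum(chi),
    symmetric = symmetric, class = c("glcm", "matrix", "array")
  )
}

#' @export
print.glcm <- function(x, ...) {
  cat(sprintf(
    "<glcm> L = %d, offset (%d, %d), %d pairs%s\n",
    attr(x, "levels"), attr(x, "offset")[1], attr(x, "offset")[2],
    attr(x, "total_pairs"), if (isTRUE(attr(x, "symmetric"))) ", symmetric" else ""
  ))
  invisible(x)
}

#' Normalize a co-occurrence matrix to a joint probability
#'
#' Divides the counts by the total pair count to obtain the joint
#' probability `p(i, j)` and precomputes every derived distribution the
#' second-order texture features need:
#'
#' * marginals `p_x(i) = sum_j p(i, j)` and `p_y(j) = sum_i p(i, j)`;
#' * sum distribution `p_{x+y}(s) = sum_{i+j=s} p(i, j)` for
#'   `s = 0 .. 2(L-1)`;
#' * difference distribution `p_{x-y}(d) = sum_{|i-j|=d} p(i, j)` for
#'   `d = 0 .. L-1`;
#' * entropies `HX`, `HY` (marginal), `HXY` (joint),
#'   `HXY1 = -sum p(i,j) log(p_x(i) p_y(j))` and
#'   `HXY2 = -sum p_x(i) p_y(j) log(p_x(i) p_y(j))`;
#' * marginal means and standard deviations.
#'
#' All logarithms are natural and `0 log 0 := 0`. `HXY2 - HXY >= 0` is the
#' mutual information between the two pixels of the pair; it drives the
#' information measures of correlation.
#'
#' @param glcm A [compute_glcm()] result with at least one counted pair.
#' @return An object of class `glcm_prob` (a list; see Details).
#' @export
normalize_glcm <- function(glcm) {
  stopifnot(inherits(glcm, "glcm"))
  total <- attr(glcm, "total_pairs")
  if (total <= 0) stop("co-occurrence matrix holds no pairs", call. = FALSE)
  p <- unclass(glcm) / total
  attributes(p) <- list(dim = dim(glcm))
  glcm_prob_from_p(p, levels = attr(glcm, "levels"), offset = attr(glcm, "offset"))
}

# Shared constructor: derive marginals, sum/difference distributions and
# entropies from an L x L probability matrix.
glcm_prob_from_p <- function(p, levels, offset = c(NA_integer_, NA_integer_)) {
  L <- levels
  px <- rowSums(p)
  py <- colSums(p)
  idx <- which(p > 0, arr.ind = TRUE)
  pv <- p[idx]
  s_group <- (idx[, 1] - 1L) + (idx[, 2] - 1L) # 0 .. 2(L-1)
  d_group <- abs(idx[, 1] - idx[, 2])          # 0 .. L-1
  p_sum <- numeric(2L * L - 1L)
  p_diff <- numeric(L)
  if (length(pv)) {
    ps <- rowsum(pv, s_group)
    p_sum[as.integer(rownames(ps)) + 1L] <- ps[, 1]
    pd <- rowsum(pv, d_group)
    p_diff[as.integer(rownames(pd)) + 1L] <- pd[, 1]
  }
  i <- 0:(L - 1L)
  mu_x <- sum(i * px); mu_y <- sum(i * py)
  sd_x <- sqrt(sum((i - mu_x)^2 * px))
  sd_y <- sqrt(sum((i - mu_y)^2 * py))
  HX <- shannon(px); HY <- shannon(py)
  HXY <- -sum(pv * log(pv))
  # HXY1 pairs the joint with the product of marginals; where p > 0 both
  # marginals are > 0, so the log is finite.
  HXY1 <- -sum(pv * log(px[idx[, 1]] * py[idx[, 2]]))
  # HXY2 is the joint entropy of the independent product p_x * p_y, which
  # separates into HX + HY.
  HXY2 <- HX + HY
  structure(
    list(
      p = p, levels = L, offset = offset,
      p_x = px, p_y = py, p_sum = p_sum, p_diff = p_diff,
      mu_x = mu_x, mu_y = mu_y, sd_x = sd_x, sd_y = sd_y,
      HX = HX, HY = HY, HXY = HXY, HXY1 = HXY1, HXY2 = HXY2
    ),
    class = "glcm_prob"
  )
}

shannon <- function(q) {
  q <- q[q > 0]
  -sum(q * log(q))
}

#' @export
print.glcm_prob <- function(x, ...) {
  cat(sprintf(
    "<glcm_prob> L = %d, HXY = %.4f, mutual information = %.4f\n",
    x$levels, x$HXY, x$HXY2 - x$HXY
  ))
  invisible(x)
}

#' Average co-occurrence structure of an image group
#'
#' Element-wise arithmetic mean of the normalized probability matrices of
#' several co-occurrence matrices (all sharing the same grey-level count
#' and offset), with the derived distributions recomputed from the mean.
#' Used to visualize how the co-occurrence mass of a burn group spreads
#' off the diagonal as speckle grows.
#'
#' @param glcms A non-empty list of [compute_glcm()] results.
#' @return A `glcm_prob` for the averaged probability matrix.
#' @export
average_glcm <- function(glcms) {
  if (!is.list(glcms) || length(glcms) == 0L) {
    stop("`glcms` must be a non-empty list of co-occurrence matrices", call. = FALSE)
  }
  if (!all(vapply(glcms, inherits, logical(1), "glcm"))) {
    stop("all elements must be `glcm` objects", call. = FALSE)
  }
  Ls <- vapply(glcms, function(g) attr(g, "levels"), integer(1))
  offs <- vapply(glcms, function(g) paste(attr(g, "offset"), collapse = ","), character(1))
  if (length(unique(Ls)) != 1L || length(unique(offs)) != 1L) {
    stop("all co-occurrence matrices must share the same levels and offset",
      call. = FALSE)
  }
  probs <- lapply(glcms, function(g) unclass(g) / attr(g, "total_pairs"))
  p_bar <- Reduce(`+`, probs) / length(probs)
  attributes(p_bar) <- list(dim = dim(p_bar))
  glcm_prob_from_p(p_bar, levels = Ls[1], offset = attr(glcms[[1]], "offset"))
}

#' Export a co-occurrence matrix as CSV
#'
#' Writes the `L x L` count grid with a one-line `#` header recording the
#' offset and grey-level count.
#'
#' @param glcm A [compute_glcm()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_glcm <- function(glcm, path) {
  stopifnot(inherits(glcm, "glcm"))
  off <- attr(glcm, "offset")
  header <- sprintf("# glcm offset=%d,%d levels=%d", off[1], off[2], attr(glcm, "levels"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(unclass(glcm), con, sep = ",", row.names = FALSE,
    col.names = FALSE)
  invisible(path)
}
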