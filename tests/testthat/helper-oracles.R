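# Independent brute-force oracles, written as plain double loops straight
# from the definitions. They intentionally share no code with the package
# internals they check.

# Pair counting by explicit enumeration over every pixel position.
naive_glcm <- function(px, L, k, l) {
  M <- nrow(px); N <- ncol(px)
  chi <- matrix(0L, L, L)
  for (m in seq_len(M)) {
    for (n in seq_len(N)) {
      m2 <- m + k; n2 <- n + l
      if (m2 >= 1 && m2 <= M && n2 >= 1 && n2 <= N) {
        i <- px[m, n]; j <- px[m2, n2]
        chi[i + 1L, j + 1L] <- chi[i + 1L, j + 1L] + 1L
      }
    }
  }
  chi
}

# All twenty catalog features evaluated directly from a joint probability
# matrix with nested loops; natural logs, 0 log 0 = 0.
oracle_features <- function(p) {
  L <- nrow(p)
  iv <- 0:(L - 1)
  px <- rowSums(p); py <- colSums(p)
  mu_x <- sum(iv * px); mu_y <- sum(iv * py)
  sd_x <- sqrt(sum((iv - mu_x)^2 * px)); sd_y <- sqrt(sum((iv - mu_y)^2 * py))
  xlogx <- function(v) if (v > 0) v * log(v) else 0

  p_sum <- numeric(2 * L - 1); p_diff <- numeric(L)
  for (i in seq_len(L)) for (j in seq_len(L)) {
    p_sum[(i - 1) + (j - 1) + 1] <- p_sum[(i - 1) + (j - 1) + 1] + p[i, j]
    p_diff[abs(i - j) + 1] <- p_diff[abs(i - j) + 1] + p[i, j]
  }
  HX <- -sum(sapply(px, xlogx)); HY <- -sum(sapply(py, xlogx))
  HXY <- 0; HXY1 <- 0; HXY2 <- 0
  for (i in seq_len(L)) for (j in seq_len(L)) {
    HXY <- HXY - xlogx(p[i, j])
    if (p[i, j] > 0 && px[i] * py[j] > 0) {
      HXY1 <- HXY1 - p[i, j] * log(px[i] * py[j])
    }
    HXY2 <- HXY2 - xlogx(px[i] * py[j])
  }

  acc <- 0; shade <- 0; prom <- 0; contr <- 0; corr_num <- 0
  dissim <- 0; energy <- 0; homog <- 0; invdiff <- 0; idmn <- 0; idn <- 0
  for (i in seq_len(L)) for (j in seq_len(L)) {
    ii <- i - 1; jj <- j - 1; v <- p[i, j]
    acc <- acc + ii * jj * v
    shade <- shade + (ii + jj - mu_x - mu_y)^3 * v
    prom <- prom + (ii + jj - mu_x - mu_y)^4 * v
    contr <- contr + (ii - jj)^2 * v
    corr_num <- corr_num + (ii - mu_x) * (jj - mu_y) * v
    dissim <- dissim + abs(ii - jj) * v
    energy <- energy + v^2
    homog <- homog + v / (1 + (ii - jj)^2)
    invdiff <- invdiff + v / (1 + abs(ii - jj))
    idmn <- idmn + v / (1 + (ii - jj)^2 / L^2)
    idn <- idn + v / (1 + abs(ii - jj) / L)
  }
  sa <- sum((0:(2 * L - 2)) * p_sum)
  sv <- sum(((0:(2 * L - 2)) - sa)^2 * p_sum)
  se <- -sum(sapply(p_sum, xlogx))
  de <- -sum(sapply(p_diff, xlogx))
  mu_d <- sum((0:(L - 1)) * p_diff)
  dv <- sum(((0:(L - 1)) - mu_d)^2 * p_diff)

  c(
    autocorrelation = acc,
    cluster_prominence = prom,
    cluster_shade = shade,
    contrast = contr,
    correlation = if (sd_x > 0 && sd_y > 0) corr_num / (sd_x * sd_y) else 0,
    difference_entropy = de,
    difference_variance = dv,
    dissimilarity = dissim,
    energy = energy,
    entropy = HXY,
    homogeneity = homog,
    imc1 = if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else 0,
    imc2 = sqrt(max(0, 1 - exp(-2 * (HXY2 - HXY)))),
    inverse_difference = invdiff,
    idmn = idmn,
    idn = idn,
    maximum_probability = max(p),
    sum_average = sa,
    sum_entropy = se,
    sum_variance = sv
  )
}

# Random joint probability matrix (strictly positive mass, sums to 1).
random_prob_matrix <- function(L) {
  m <- matrix(stats::rexp(L * L), L, L)
  m / sum(m)
}

# Random small test image.
random_image <- function(M, N, L) {
  grey_image(matrix(sample.int(L, M * N, replace = TRUE) - 1L, M, N), levels = L)
}
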