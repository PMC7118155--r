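#' Specification of a synthetic speckle phantom
#'
#' Describes one synthetic B-mode-like greyscale phantom. The healthy
#' background is Rayleigh-envelope speckle (the standard model for fully
#' developed ultrasound speckle) scaled to a mean grey level of about
#' 120 and smoothed to a correlation length of a couple of pixels, as a
#' resolution cell spans several pixels in a real scan: horizontally
#' adjacent background pixels are strongly correlated and co-occur near
#' the GLCM diagonal. On top of it, dark elliptical blobs of *rough*
#' (unsmoothed) low-intensity Rayleigh texture emulate the
#' strong-scattering speckle regions that thermal damage produces: water
#' trapped in the tissue evaporates, and the vapour-filled pores contrast
#' acoustically with the surrounding tissue. The blobs grow in number and
#' size with the severity parameter `s` in `[0, 1]` and appear
#' progressively along image depth — at low severity they are confined to
#' the deeper part of the frame, at high severity they reach close to the
#' surface. Together these spread the co-occurrence mass of the low-grey
#' band off the diagonal as severity rises: contrast, difference
#' variance, the nonlinear dependency (second information measure of
#' correlation) and sum entropy grow, while correlation, homogeneity,
#' inverse difference and maximum probability fall.
#'
#' Severity maps affinely to the generator parameters:
#' * expected blob density `rho(s) = density_max * s` blobs per pixel
#'   (so severity 0 has no blobs);
#' * mean blob radius `1.5 + 2.5 s` pixels (spread 30% of the mean);
#' * depth onset fraction `0.6 (1 - s)`: blob centres are placed only
#'   below that fraction of the image height;
#' * blob core intensity drawn uniformly from `dark_range` (default
#'   `[10, 60]`, inside the low-intensity band 0-70 that characterizes
#'   the speckle regions).
#'
#' @param severity Burn severity in `[0, 1]`.
#' @param height,width Image size in pixels (depth runs along rows). The
#'   default 132 x 176 corresponds to a 1.1 cm x 1.5 cm field sampled at
#'   about 85 um per pixel.
#' @param levels Grey-level count (default 256).
#' @param base_mean Mean grey level of the Rayleigh background.
#' @param density_max Blob density at severity 1 (blobs per pixel).
#' @param dark_range Core intensity range of the dark blobs.
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(severity, height = 132L, width = 176L, levels = 256L,
                         base_mean = 120, density_max = 0.004,
                         dark_range = c(10, 60), seed = 1L) {
  if (severity < 0 || severity > 1) {
    stop("`severity` must lie in [0, 1]", call. = FALSE)
  }
  if (height < 1L || width < 1L) {
    stop("phantom must have positive area", call. = FALSE)
  }
  structure(
    list(
      severity = severity, height = as.integer(height),
      width = as.integer(width), levels = as.integer(levels),
      base_mean = base_mean, density = density_max * severity,
      radius_mean = 1.5 + 2.5 * severity,
      radius_sd = 0.3 * (1.5 + 2.5 * severity),
      depth_onset = 0.6 * (1 - severity),
      dark_range = dark_range, seed = as.integer(seed)
    ),
    class = "phantom_spec"
  )
}

#' Generate a synthetic speckle phantom
#'
#' Draws one greyscale phantom from a [phantom_spec()]: Rayleigh-style
#' background speckle, then a Poisson number of dark elliptical blobs
#' with smoothed edges, placed below the severity-dependent depth onset.
#' Deterministic given the spec's seed.
#'
#' @param spec A [phantom_spec()].
#' @return A [grey_image()] of `height x width` pixels.
#' @export
#' @examples
#' img <- generate_phantom(phantom_spec(severity = 0.8, seed = 42))
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  M <- spec$height; N <- spec$width
  with_seed(spec$seed, {
    # Rayleigh envelope: mean sigma * sqrt(pi/2) == base_mean. The healthy
    # background is smoothed to emulate the spatial correlation of fully
    # developed speckle (the resolution cell spans several pixels), so
    # horizontally adjacent pixels co-occur near the diagonal of the GLCM.
    sigma <- spec$base_mean / sqrt(pi / 2)
    base <- smooth_gaussian(matrix(sigma * sqrt(-2 * log(stats::runif(M * N))), M, N))
    base <- base * (spec$base_mean / mean(base))
    # The burn-induced speckle regions are rough, low-intensity scattering
    # zones: an *unsmoothed* Rayleigh field provides their texture.
    dark_field <- matrix(sigma * sqrt(-2 * log(stats::runif(M * N))), M, N)
    img <- base
    n_blobs <- stats::rpois(1, spec$density * M * N)
    if (n_blobs > 0) {
      min_row <- max(1, ceiling(spec$depth_onset * M))
      rows <- seq_len(M)
      cols <- seq_len(N)
      for (b in seq_len(n_blobs)) {
        cr <- stats::runif(1, min_row, M)
        cc <- stats::runif(1, 1, N)
        rx <- max(0.8, stats::rnorm(1, spec$radius_mean, spec$radius_sd))
        ry <- max(0.8, stats::rnorm(1, spec$radius_mean, spec$radius_sd))
        theta <- stats::runif(1, 0, pi)
        dark <- stats::runif(1, spec$dark_range[1], spec$dark_range[2])
        # bounding box, then smoothed elliptical blend toward the dark core
        rmax <- 1.2 * max(rx, ry)
        rr <- rows[rows >= cr - rmax & rows <= cr + rmax]
        cc_ix <- cols[cols >= cc - rmax & cols <= cc + rmax]
        if (!length(rr) || !length(cc_ix)) next
        dr <- outer(rr - cr, rep(1, length(cc_ix)))
        dc <- outer(rep(1, length(rr)), cc_ix - cc)
        u <- (dr * cos(theta) + dc * sin(theta)) / rx
        v <- (-dr * sin(theta) + dc * cos(theta)) / ry
        d <- sqrt(u^2 + v^2)
        w <- pmin(1, pmax(0, (1.2 - d) / 0.4)) # full core for d <= 0.8
        patch <- img[rr, cc_ix, drop = FALSE]
        # full-variance rough texture folded about zero so the dark zones
        # reach into the blackest greys without piling an atom at 0
        target <- abs(dark + dark_field[rr, cc_ix, drop = FALSE] - spec$base_mean)
        img[rr, cc_ix] <- (1 - w) * patch + w * pmin(patch, target)
      }
    }
    px <- round(img)
    px <- pmin(pmax(px, 0), spec$levels - 1L)
    grey_image(px, levels = spec$levels,
      source_id = sprintf("phantom(severity=%.2f, seed=%d)", spec$severity, spec$seed))
  })
}

# Separable Gaussian smoothing with replicated edges. The default width
# gives the background speckle a neighbour autocorrelation of about 0.95,
# emulating a resolution cell spanning a few pixels.
smooth_gaussian <- function(m, sd = 2.2) {
  half <- ceiling(3 * sd)
  k <- stats::dnorm(-half:half, sd = sd)
  k <- k / sum(k)
  conv1 <- function(x) { # along the first dimension
    n <- nrow(x)
    out <- 0
    for (t in -half:half) {
      idx <- pmin(pmax(seq_len(n) + t, 1L), n)
      out <- out + k[t + half + 1L] * x[idx, , drop = FALSE]
    }
    out
  }
  t(conv1(t(conv1(m))))
}

#' Generate a labeled multi-class phantom dataset
#'
#' Draws `n_per_class` phantoms for each severity level, with a
#' deterministic per-image seed derived from `seed`. Labels default to
#' `sev<severity>` or the names of `severities` if given. When `dir` is
#' supplied the images are written as PNG files next to a `manifest.csv`
#' and a JSON sidecar recording the full per-class phantom spec.
#'
#' @param severities Distinct severity values in `[0, 1]`, one per class.
#'   The default four-class ladder `c(0.1, 0.4, 0.6, 0.9)` is separable
#'   but leaves the two middle classes closest, so occasional confusions
#'   concentrate there.
#' @param n_per_class Images per class (>= 2).
#' @param seed Master seed for the per-image seed stream.
#' @param dir Optional output directory for PNGs + manifest.
#' @param ... Passed to [phantom_spec()] (image size, density, ...).
#' @return A list with `images` (named list of [grey_image()]s),
#'   `manifest` (tibble `sample_id`, `label`, `severity`, and `path` when
#'   written to `dir`), and `specs` (per-class [phantom_spec()] with
#'   seed 0 as the class template).
#' @export
generate_dataset <- function(severities = c(0.1, 0.4, 0.6, 0.9),
                             n_per_class = 30L, seed = 1L, dir = NULL, ...) {
  if (anyDuplicated(severities)) {
    stop("severity values must be distinct", call. = FALSE)
  }
  if (n_per_class < 2L) stop("`n_per_class` must be >= 2", call. = FALSE)
  labels <- names(severities)
  if (is.null(labels)) labels <- sprintf("sev%.2f", severities)
  n_total <- length(severities) * n_per_class
  img_seeds <- with_seed(seed, sample.int(.Machine$integer.max, n_total))
  images <- vector("list", n_total)
  ids <- character(n_total)
  lab <- character(n_total)
  sev <- numeric(n_total)
  t <- 0L
  for (ci in seq_along(severities)) {
    for (r in seq_len(n_per_class)) {
      t <- t + 1L
      sp <- phantom_spec(severity = severities[ci], seed = img_seeds[t], ...)
      images[[t]] <- generate_phantom(sp)
      ids[t] <- sprintf("%s_%03d", labels[ci], r)
      lab[t] <- labels[ci]
      sev[t] <- severities[ci]
    }
  }
  names(images) <- ids
  manifest <- tibble::tibble(sample_id = ids, label = lab, severity = sev)
  specs <- lapply(seq_along(severities), function(ci) {
    phantom_spec(severity = severities[ci], seed = 0L, ...)
  })
  names(specs) <- labels
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- file.path(dir, paste0(ids, ".png"))
    purrr::walk2(images, paths, write_grey_image)
    manifest$path <- paths
    write_manifest(manifest, file.path(dir, "manifest.csv"))
    jsonlite::write_json(
      lapply(specs, unclass),
      file.path(dir, "phantom_specs.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  list(images = images, manifest = manifest, specs = specs)
}
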