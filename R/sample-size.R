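#' Minimum sample size for a diagnostic classification study
#'
#' Buderer-style sample-size bound for a diagnostic test that must
#' demonstrate target sensitivity and specificity within a maximum
#' marginal error at a given confidence level. With prevalence `P`,
#' critical value `z` and marginal error `d`, the bound is the larger of
#' the sensitivity- and specificity-driven requirements,
#'
#' `n = max( z^2 sn (1 - sn) / (d^2 P),  z^2 sp (1 - sp) / (d^2 (1 - P)) )`,
#'
#' rounded up to the next integer.
#'
#' @param sensitivity,specificity Target values in `(0, 1]`.
#' @param prevalence Expected positive fraction `P`, strictly inside
#'   `(0, 1)`.
#' @param margin Maximum marginal error `d > 0`.
#' @param alpha Confidence level (default 0.05), used only to derive the
#'   default critical value.
#' @param z Standard normal critical value `z_{1-alpha/2}`; override to
#'   use a rounded conventional value such as 1.96.
#' @return The minimum sample size, as an integer.
#' @export
#' @examples
#' min_sample_size(0.95, 0.95, prevalence = 0.4, margin = 0.1, z = 1.96)
min_sample_size <- function(sensitivity, specificity, prevalence, margin,
                            alpha = 0.05, z = stats::qnorm(1 - alpha / 2)) {
  if (sensitivity <= 0 || sensitivity > 1 || specificity <= 0 || specificity > 1) {
    stop("sensitivity and specificity must lie in (0, 1]", call. = FALSE)
  }
  if (prevalence <= 0 || prevalence >= 1) {
    stop("prevalence must lie strictly between 0 and 1", call. = FALSE)
  }
  if (margin <= 0) stop("`margin` must be positive", call. = FALSE)
  if (z <= 0) stop("critical value `z` must be positive", call. = FALSE)
  n_sens <- z^2 * sensitivity * (1 - sensitivity) / (margin^2 * prevalence)
  n_spec <- z^2 * specificity * (1 - specificity) / (margin^2 * (1 - prevalence))
  as.integer(ceiling(max(n_sens, n_spec)))
}
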