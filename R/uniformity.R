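#' Rayleigh test of circular uniformity
#'
#' Tests uniformity against a unimodal von Mises alternative. The reported
#' statistic is the mean vector length `r`; the p-value uses the standard
#' large-sample approximation
#' `p = exp(sqrt(1 + 4n + 4(n^2 - R^2)) - (1 + 2n))` with `R = n*r`.
#'
#' @param x Angles in radians (numeric vector or `circular_sample`).
#' @return A list of class `uniformity_result` with `test`, `statistic`
#'   (the mean vector length), `p_value`, `n` and `null_method = "analytic"`.
#' @export
rayleigh_test <- function(x) {
  a <- as_angles(x)
  n <- length(a)
  if (n < 2) stop("Rayleigh test needs n >= 2", call. = FALSE)
  r <- sqrt(sum(cos(a))^2 + sum(sin(a))^2) / n
  R <- n * r
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - R^2)) - (1 + 2 * n))
  structure(list(test = "rayleigh", statistic = r,
                 p_value = min(max(p, 0), 1), n = n,
                 null_method = "analytic", n_sim = NA_integer_,
                 seed = NA_integer_),
            class = "uniformity_result")
}

#' Hermans-Rasson test statistic
#'
#' The Hermans-Rasson statistic (in the modern form with the 2.895 sine
#' correction term) retains power against multimodal departures from
#' uniformity where the Rayleigh test does not:
#' `T = (1/n) * sum_{i,j} [ |pi - |t_i - t_j|| - pi/2
#'       - 2.895 * (|sin(t_i - t_j)| - 2/pi) ]`.
#' The statistic is invariant under joint rotation of the sample.
#'
#' @param x Angles in radians.
#' @return The statistic `T` (larger values mean stronger departure from
#'   uniformity).
#' @export
hr_statistic <- function(x) {
  a <- as_angles(x)
  n <- length(a)
  d <- outer(a, a, "-")
  sum(abs(pi - abs(d)) - pi / 2 - 2.895 * (abs(sin(d)) - 2 / pi)) / n
}

#' Hermans-Rasson test of circular uniformity
#'
#' The null distribution of [hr_statistic()] has no convenient closed form;
#' the p-value is obtained by Monte Carlo simulation of uniform samples of
#' the same size: `p = (1 + #{T_sim >= T_obs}) / (n_sim + 1)`.
#'
#' @param x Angles in radians.
#' @param n_sim Number of uniform null simulations (>= 999 recommended; a
#'   smaller value triggers a warning).
#' @param seed Optional integer seed for the null simulations.
#' @param null_stats Optional precomputed vector of null statistics for this
#'   sample size (e.g. shared across many tests of equal `n`); when supplied,
#'   `n_sim` and `seed` are ignored.
#' @return A list of class `uniformity_result` with `test`, `statistic` (T),
#'   `p_value`, `n`, `null_method = "monte_carlo"`, `n_sim`, `seed`.
#' @export
hermans_rasson_test <- function(x, n_sim = 999, seed = NULL,
                                null_stats = NULL) {
  a <- as_angles(x)
  n <- length(a)
  if (n < 4) stop("Hermans-Rasson test needs n >= 4", call. = FALSE)
  t_obs <- hr_statistic(a)
  if (is.null(null_stats)) {
    if (n_sim < 999) warning("n_sim < 999 gives a coarse p-value")
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv)) {
        get(".Random.seed", .GlobalEnv)
      } else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed)
    }
    null_stats <- hr_null_sample(n, n_sim)
  }
  p <- (1 + sum(null_stats >= t_obs)) / (length(null_stats) + 1)
  structure(list(test = "hermans_rasson", statistic = t_obs, p_value = p,
                 n = n, null_method = "monte_carlo",
                 n_sim = length(null_stats),
                 seed = if (is.null(seed)) NA_integer_ else seed),
            class = "uniformity_result")
}

#' Simulate the Hermans-Rasson null distribution
#'
#' Draws `n_sim` uniform circular samples of size `n` and returns their
#' statistics; useful to share one null sample across many tests of the
#' same size.
#'
#' @param n Sample size.
#' @param n_sim Number of simulated statistics.
#' @return Numeric vector of length `n_sim`.
#' @export
hr_null_sample <- function(n, n_sim) {
  vapply(seq_len(n_sim),
         function(i) hr_statistic(stats::runif(n, 0, 2 * pi)),
         numeric(1))
}

#' Choose the uniformity test implied by the best-fit model
#'
#' Uniform and unimodal best-fit distributions are tested with the Rayleigh
#' test; bimodal (axial or non-axial) best fits with the Hermans-Rasson
#' test, which keeps power against multimodal alternatives.
#'
#' @param best_fit A `mixture_fit` (typically `select_model(x)$best`).
#' @return `"rayleigh"` or `"hermans_rasson"`.
#' @export
choose_uniformity_test <- function(best_fit) {
  if (!inherits(best_fit, "mixture_fit")) {
    stop("`best_fit` must be a mixture_fit", call. = FALSE)
  }
  if (best_fit$modality %in% c("uniform", "unimodal")) "rayleigh"
  else "hermans_rasson"
}

#' @export
print.uniformity_result <- function(x, ...) {
  cat(sprintf("%s test: statistic = %.4f, p = %.4g (n = %d, %s)\n",
              x$test, x$statistic, x$p_value, x$n, x$null_method))
  invisible(x)
}
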