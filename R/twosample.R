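#' Construct a grouped circular sample
#'
#' Monthly (or otherwise binned) counts around the circle, the form in which
#' herbarium collection dates enter the two-sample Watson U2 test.
#'
#' @param counts Nonnegative integer vector of per-bin counts (12 bins for
#'   months, January first).
#' @param bin_labels Optional labels, defaults to `1:length(counts)`.
#' @return An object of class `grouped_sample` with `counts`, `bin_labels`
#'   and total `n`.
#' @export
grouped_sample <- function(counts, bin_labels = seq_along(counts)) {
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  structure(list(counts = as.integer(counts),
                 bin_labels = bin_labels,
                 n = as.integer(sum(counts))),
            class = "grouped_sample")
}

#' Group months into a 12-bin circular sample
#'
#' @param months Integer vector of months 1..12.
#' @return A `grouped_sample` with 12 bins.
#' @export
group_months <- function(months) {
  if (length(months) && (any(is.na(months)) || any(months < 1 | months > 12))) {
    stop("months must be in 1..12", call. = FALSE)
  }
  grouped_sample(tabulate(months, nbins = 12L), bin_labels = 1:12)
}

as_grouped <- function(x) {
  if (inherits(x, "grouped_sample")) return(x)
  if (is.numeric(x)) return(group_months(x))
  stop("expected a grouped_sample or a vector of months", call. = FALSE)
}

# Grouped (ties-corrected) two-sample Watson U2 statistic from two count
# vectors over the same bins:
#   U2 = (n1*n2/N^2) * [sum(t_k * d_k^2) - (sum(t_k * d_k))^2 / N]
# with d_k the difference in cumulative relative frequencies and t_k the
# pooled count in bin k. The centering term makes the statistic invariant
# to the choice of starting bin (cyclic origin).
watson_u2_stat <- function(c1, c2) {
  n1 <- sum(c1); n2 <- sum(c2); N <- n1 + n2
  d <- cumsum(c1) / n1 - cumsum(c2) / n2
  t <- c1 + c2
  (n1 * n2 / N^2) * (sum(t * d^2) - sum(t * d)^2 / N)
}

# Asymptotic tail of Watson's U2: P(U2 > u) = 2 * sum (-1)^(m-1) exp(-2 m^2 pi^2 u)
watson_u2_pasym <- function(u, terms = 20) {
  m <- seq_len(terms)
  p <- 2 * sum((-1)^(m - 1) * exp(-2 * m^2 * pi^2 * u))
  min(max(p, 0), 1)
}

#' Two-sample Watson U2 test for grouped circular data
#'
#' Tests whether two binned circular samples (e.g. monthly counts of
#' flowering specimens in two time intervals) come from the same
#' distribution, using the ties-corrected grouped form of Watson's U2.
#' The p-value is obtained by permutation of the pooled bin memberships
#' (default) or from the asymptotic U2 tail series.
#'
#' @param s1,s2 `grouped_sample`s over the same bins, or vectors of months.
#' @param n_perm Number of permutations for the permutation null.
#' @param seed Optional integer seed for the permutations.
#' @param method `"permutation"` (default) or `"asymptotic"`.
#' @return A list of class `twosample_result` with `u2`, `p_value`,
#'   `n1`, `n2` and `null_method`. Symmetric in the order of its arguments.
#' @export
watson_u2_grouped <- function(s1, s2, n_perm = 9999, seed = NULL,
                              method = c("permutation", "asymptotic")) {
  method <- match.arg(method)
  g1 <- as_grouped(s1); g2 <- as_grouped(s2)
  if (length(g1$counts) != length(g2$counts)) {
    stop("samples must share the same bin structure", call. = FALSE)
  }
  if (g1$n == 0 || g2$n == 0) stop("both samples must be non-empty", call. = FALSE)
  u2 <- watson_u2_stat(g1$counts, g2$counts)
  if (method == "asymptotic") {
    p <- watson_u2_pasym(u2)
  } else {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv)) {
        get(".Random.seed", .GlobalEnv)
      } else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed)
    }
    pooled <- rep(seq_along(g1$counts), g1$counts + g2$counts)
    N <- g1$n + g2$n
    nbin <- length(g1$counts)
    nsub <- min(g1$n, g2$n)  # permute the smaller group: symmetric in order
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      idx <- sample.int(N, nsub)
      c1 <- tabulate(pooled[idx], nbins = nbin)
      c2 <- tabulate(pooled[-idx], nbins = nbin)
      if (watson_u2_stat(c1, c2) >= u2 - 1e-12) exceed <- exceed + 1L
    }
    p <- (1 + exceed) / (n_perm + 1)
  }
  structure(list(u2 = u2, p_value = p, n1 = g1$n, n2 = g2$n,
                 null_method = method,
                 n_perm = if (method == "permutation") n_perm else NA_integer_),
            class = "twosample_result")
}

#' @export
print.twosample_result <- function(x, ...) {
  cat(sprintf("Watson U2 (grouped): U2 = %.4f, p = %.4g (n1 = %d, n2 = %d, %s)\n",
              x$u2, x$p_value, x$n1, x$n2, x$null_method))
  invisible(x)
}

#' Pairwise Watson U2 comparisons between time intervals
#'
#' Runs the grouped two-sample Watson U2 test for every unordered pair of
#' intervals and flags significance at `alpha`.
#'
#' @param samples Named list of month vectors (1..12) or `grouped_sample`s,
#'   one per interval, in display order.
#' @param n_perm,seed,method Passed to [watson_u2_grouped()].
#' @param alpha Significance threshold for the flag matrix.
#' @param p_adjust Multiple-testing adjustment method for the flagged
#'   p-values (`"none"` by default, matching the analysis convention;
#'   `"holm"` available).
#' @return A list of class `interval_comparison` with matrices `u2`, `p`,
#'   `significant`, and a long-format data frame `pairs`. Pairs involving an
#'   empty interval are reported as untestable (`NA`).
#' @export
interval_comparison_matrix <- function(samples, n_perm = 9999, seed = NULL,
                                       method = c("permutation", "asymptotic"),
                                       alpha = 0.05,
                                       p_adjust = c("none", "holm")) {
  method <- match.arg(method)
  p_adjust <- match.arg(p_adjust)
  if (length(samples) < 2) stop("need at least 2 intervals", call. = FALSE)
  labs <- names(samples) %||% as.character(seq_along(samples))
  k <- length(samples)
  u2 <- p <- matrix(NA_real_, k, k, dimnames = list(labs, labs))
  rows <- list()
  seed_i <- 0L
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    gi <- as_grouped(samples[[i]]); gj <- as_grouped(samples[[j]])
    seed_i <- seed_i + 1L
    if (gi$n == 0 || gj$n == 0) {
      rows[[length(rows) + 1]] <- data.frame(
        interval1 = labs[i], interval2 = labs[j], u2 = NA_real_,
        p_value = NA_real_, n1 = gi$n, n2 = gj$n, testable = FALSE)
      next
    }
    res <- watson_u2_grouped(gi, gj, n_perm = n_perm,
                             seed = if (is.null(seed)) NULL else seed + seed_i,
                             method = method)
    u2[i, j] <- u2[j, i] <- res$u2
    p[i, j] <- p[j, i] <- res$p_value
    rows[[length(rows) + 1]] <- data.frame(
      interval1 = labs[i], interval2 = labs[j], u2 = res$u2,
      p_value = res$p_value, n1 = gi$n, n2 = gj$n, testable = TRUE)
  }
  pairs <- do.call(rbind, rows)
  pairs$p_adjusted <- stats::p.adjust(pairs$p_value, method = p_adjust)
  pairs$significant <- !is.na(pairs$p_adjusted) & pairs$p_adjusted < alpha
  sig <- matrix(NA, k, k, dimnames = list(labs, labs))
  for (r in seq_len(nrow(pairs))) {
    i <- match(pairs$interval1[r], labs); j <- match(pairs$interval2[r], labs)
    sig[i, j] <- sig[j, i] <- pairs$significant[r]
  }
  structure(list(u2 = u2, p = p, significant = sig, pairs = pairs,
                 alpha = alpha, method = method),
            class = "interval_comparison")
}

#' @export
print.interval_comparison <- function(x, ...) {
  cat("Pairwise Watson U2 between intervals (alpha =", x$alpha, ")\n")
  print(round(x$u2, 4))
  invisible(x)
}

#' Chi-square contingency analysis with Pearson residuals
#'
#' Tests independence of a month-by-interval (or any) contingency table and
#' returns the Pearson residual matrix `(O - E)/sqrt(E)` used to display
#' which cells drive the association. Rows or columns with zero margins are
#' dropped with a warning.
#'
#' @param counts Nonnegative integer matrix with at least two non-degenerate
#'   rows and columns.
#' @return A list with `statistic`, `df`, `p_value`, `residuals`, `expected`
#'   and the (possibly reduced) `observed` table.
#' @export
contingency_residuals <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  keep_r <- rowSums(counts) > 0
  keep_c <- colSums(counts) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warning("dropping rows/columns with zero margins")
    counts <- counts[keep_r, keep_c, drop = FALSE]
  }
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    stop("need at least 2 rows and 2 columns with nonzero margins",
         call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value), residuals = ct$residuals,
       expected = ct$expected, observed = counts)
}
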