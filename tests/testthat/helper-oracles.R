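# Independent oracles used to check the package implementations.

# Inverse of A(kappa) = I1(kappa)/I0(kappa) by root finding on the Bessel
# ratio (independent of the package's moment approximation).
a1inv_oracle <- function(r) {
  if (r < 1e-12) return(0)
  f <- function(k) besselI(k, 1) / besselI(k, 0) - r
  stats::uniroot(f, c(1e-8, 700), tol = 1e-10)$root
}

# Direct transcription of the grouped two-sample Watson U2 definition:
# loops and explicit cumulative relative frequencies.
watson_u2_oracle <- function(c1, c2) {
  n1 <- sum(c1); n2 <- sum(c2); N <- n1 + n2
  K <- length(c1)
  dk <- numeric(K); tk <- numeric(K)
  A <- 0; B <- 0
  for (k in 1:K) {
    A <- A + c1[k]; B <- B + c2[k]
    dk[k] <- A / n1 - B / n2
    tk[k] <- c1[k] + c2[k]
  }
  s1 <- 0; s2 <- 0
  for (k in 1:K) {
    s1 <- s1 + tk[k] * dk[k]^2
    s2 <- s2 + tk[k] * dk[k]
  }
  (n1 * n2 / N^2) * (s1 - s2^2 / N)
}

# Exhaustive permutation p-value for the grouped Watson U2 on a small
# pooled sample: enumerates every split of the pooled observations.
watson_u2_exact_p <- function(c1, c2) {
  pooled <- rep(seq_along(c1), c1 + c2)
  N <- length(pooled); n1 <- sum(c1)
  obs <- watson_u2_oracle(c1, c2)
  splits <- utils::combn(N, n1)
  hits <- 0
  for (j in seq_len(ncol(splits))) {
    a <- tabulate(pooled[splits[, j]], nbins = length(c1))
    b <- tabulate(pooled[-splits[, j]], nbins = length(c1))
    if (watson_u2_oracle(a, b) >= obs - 1e-12) hits <- hits + 1
  }
  hits / ncol(splits)
}

# Numerical check that a mixture density integrates to one.
mixture_mass <- function(code, params) {
  stats::integrate(function(t) exp(mixture_logpdf(t, code, params)),
                   0, 2 * pi, rel.tol = 1e-9)$value
}

# Probability mass of a mixture model over a month arc, by quadrature.
arc_mass <- function(code, params, month) {
  lo <- (month - 1) * pi / 6
  stats::integrate(function(t) exp(mixture_logpdf(t, code, params)),
                   lo, lo + pi / 6, rel.tol = 1e-8)$value
}

# Small record data frame builder for records-module tests.
make_records <- function(n = 3, ...) {
  base <- data.frame(
    record_id = sprintf("R%03d", seq_len(n)),
    species = rep("Testia exempli", n),
    collector = sprintf("Collector %d", seq_len(n)),
    collector_number = as.character(seq_len(n)),
    year = rep(1990L, n), month = rep(6L, n), day = rep(15L, n),
    locality = sprintf("Town %d", seq_len(n)),
    latitude = rep(-23.5, n), longitude = rep(-46.6, n),
    flowering = rep(TRUE, n), fruiting = rep(FALSE, n),
    sterile = rep(FALSE, n),
    stringsAsFactors = FALSE
  )
  mods <- list(...)
  for (nm in names(mods)) base[[nm]] <- mods[[nm]]
  base
}

write_records_file <- function(records, sep = ",") {
  path <- tempfile(fileext = if (sep == ",") ".csv" else ".tsv")
  utils::write.table(records, path, sep = sep, row.names = FALSE, quote = TRUE)
  path
}

# Tiny deterministic climate table: values encode (year, month) so lag
# arithmetic can be verified exactly.
toy_climate <- function(years = 1988:1991, lat = -23.5, lon = -46.6) {
  grid <- expand.grid(year = years, month = 1:12)
  climate_table(data.frame(
    latitude = lat, longitude = lon,
    year = grid$year, month = grid$month,
    precip_mm = grid$year - 1900 + grid$month / 100,
    tmax_C = 25 + grid$month / 10,
    tmin_C = 15 + grid$month / 10
  ))
}
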