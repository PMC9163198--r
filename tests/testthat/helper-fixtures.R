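# Shared fixtures and independent oracle helpers. Oracles are deliberately
# naive (explicit loops, closed forms) and never call the code paths they
# check.

# Pearson correlation straight from the covariance definition
pearson_oracle <- function(a, b) {
  ca <- a - mean(a); cb <- b - mean(b)
  sum(ca * cb) / sqrt(sum(ca^2) * sum(cb^2))
}

# circular autocorrelation by direct lag products (about the mean)
circular_acf_oracle <- function(x) {
  n <- length(x)
  xc <- x - mean(x)
  vapply(0:(n - 1), function(lag)
    sum(xc * xc[(seq_len(n) - 1 + lag) %% n + 1]), numeric(1))
}

# periodogram by direct DFT sums, no fft()
periodogram_oracle <- function(x) {
  n <- length(x)
  t <- seq_len(n) - 1
  vapply(0:(n - 1), function(k) {
    Mod(sum(x * exp(-2i * pi * k * t / n)))^2
  }, numeric(1))
}

# discretized wavelet modulus ratio by explicit loops over cells, with the
# truncated-and-renormalized Gaussian kernel written out longhand
wmr_loop_oracle <- function(fields) {
  csum <- Reduce(`+`, lapply(fields, function(f) f$coef))
  msum <- Reduce(`+`, lapply(fields, function(f) Mod(f$coef)))
  n_t <- length(fields[[1]]$times)
  scales <- fields[[1]]$scales
  rho <- matrix(NA_real_, n_t, length(scales))
  for (j in seq_along(scales)) {
    s <- scales[j]
    h <- max(1L, ceiling(4 * s))
    for (t in seq_len(n_t)) {
      idx <- max(1L, t - h):min(n_t, t + h)
      w <- exp(-0.5 * ((idx - t) / s)^2)
      w <- w / sum(w)
      num <- sum(w * Mod(csum[idx, j]))
      den <- sum(w * msum[idx, j])
      rho[t, j] <- num / den
    }
  }
  coi <- outer(fields[[1]]$coi_scale, scales, `>=`)
  rho[!coi] <- NA_real_
  rho
}

# 3 species x 6 years toy table with hand-checkable integers
toy_table <- function() {
  seasonal_series(cbind(x1 = c(2, 5, 3, 8, 6, 4),
                        x2 = c(1, 2, 2, 6, 3, 2),
                        x3 = c(9, 4, 7, 2, 5, 6)),
                  years = 1991:1996, season = "warm")
}

# seasonal sinusoid plus fixed-seed noise, the standard monthly fixture
seasonal_series_fixture <- function(n_months = 240, seed = 42) {
  set.seed(seed)
  10 + 5 * sin(2 * pi * seq_len(n_months) / 12) + rnorm(n_months)
}

season_years_oracle <- function(years, season) {
  ys <- sort(unique(years))
  if (season == "warm") ys else ys[ys + 1 <= max(ys)]
}

season_years_of <- function(s) as.integer(rownames(s))

random_records <- function(n, years, species, seed) {
  set.seed(seed)
  data.frame(year = sample(years, n, replace = TRUE),
             month = sample(1:12, n, replace = TRUE),
             species = sample(species, n, replace = TRUE),
             count = rpois(n, 5))
}
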