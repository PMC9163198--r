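#' Default dyadic scale grid
#'
#' Dyadic scales with 12 voices per octave from 2 months up to a quarter of
#' the series length, which resolves sub-seasonal (2-4 month), annual and
#' multi-year variability in multi-decade monthly records.
#'
#' @param n_time series length in months.
#' @param s0 smallest scale (months, default 2).
#' @param voices voices per octave (default 12).
#' @param max_fraction largest scale as a fraction of the series length
#'   (default 1/4).
#' @return increasing numeric vector of scales in months.
#' @export
default_scales <- function(n_time, s0 = 2, voices = 12, max_fraction = 1 / 4) {
  smax <- n_time * max_fraction
  if (smax < s0) stop("series too short for the requested scale range")
  j <- 0:floor(voices * log2(smax / s0))
  s0 * 2^(j / voices)
}

#' Continuous Morlet wavelet transform
#'
#' Transforms a monthly series with the analytic Morlet wavelet (a complex
#' exponential under a Gaussian envelope, central frequency `omega0 = 6` by
#' default) using the FFT algorithm and unit-energy normalization of
#' Torrence & Compo. The series is mean-removed and zero-padded to the next
#' power of two; the cone of influence records, for each time point, the
#' largest scale whose coefficient is free of edge effects (e-folding time
#' `sqrt(2) * s` of the wavelet envelope).
#'
#' The scale of maximum response to a pure sinusoid of period P is
#' `P * (omega0 + sqrt(2 + omega0^2)) / (4 * pi)` (the equivalent Fourier
#' period relation), about `0.968 * P` for `omega0 = 6`.
#'
#' @param x numeric vector (monthly values), length >= 16.
#' @param scales increasing positive scales in months; default
#'   [default_scales()]. Must lie in `[2, T/2]`.
#' @param omega0 Morlet central frequency (default 6, admissible).
#' @param dt sampling step (months, default 1).
#' @return object of class `wavelet_field`: list with complex `coef`
#'   (time x scale), `scales`, `times`, `coi_scale` (largest reliable scale
#'   per time), `omega0`.
#' @export
morlet_cwt <- function(x, scales = NULL, omega0 = 6, dt = 1) {
  n <- length(x)
  if (n < 16L) stop("wavelet transform needs at least 16 time points")
  if (is.null(scales)) scales <- default_scales(n * dt)
  if (any(scales < 2 * dt) || any(scales > n * dt / 2))
    stop("scales must lie within [2, T/2] months")
  if (is.unsorted(scales, strictly = TRUE)) stop("scales must be strictly increasing")
  np <- 2^ceiling(log2(n))
  xhat <- stats::fft(c(x - mean(x), rep(0, np - n)))
  k <- 0:(np - 1)
  omega <- ifelse(k <= np / 2, k, k - np) * (2 * pi / (np * dt))
  coef <- matrix(0i, n, length(scales))
  for (j in seq_along(scales)) {
    s <- scales[j]
    # unit-energy analytic Morlet daughter in the frequency domain
    psi_hat <- pi^(-1 / 4) * sqrt(2 * pi * s / dt) *
      exp(-(s * omega - omega0)^2 / 2) * (omega > 0)
    w <- stats::fft(xhat * psi_hat, inverse = TRUE) / np
    coef[, j] <- w[seq_len(n)]
  }
  dist_edge <- pmin(seq_len(n) - 1L, n - seq_len(n)) * dt
  structure(list(coef = coef, scales = scales, times = seq_len(n) * dt,
                 coi_scale = dist_edge / sqrt(2), omega0 = omega0),
            class = "wavelet_field")
}

#' Scale of maximum Morlet response to a sinusoid of period `period`
#' @param period oscillation period (months).
#' @param omega0 Morlet central frequency.
#' @return equivalent scale in months.
#' @export
period_to_scale <- function(period, omega0 = 6) {
  period * (omega0 + sqrt(2 + omega0^2)) / (4 * pi)
}

# Gaussian smoothing in time with sd `sd`, kernel truncated at +/- 4 sd and
# renormalized over the in-range support (edge-aware). FFT convolution of the
# zero-padded signal divided by the convolved kernel mass is algebraically the
# truncated-and-renormalized weighted mean.
gaussian_smooth <- function(v, sd) {
  n <- length(v)
  h <- max(1L, ceiling(4 * sd))
  w <- stats::dnorm(seq(-h, h), sd = sd)
  num <- stats::convolve(v, w, type = "open")[(h + 1):(h + n)]
  mass <- stats::convolve(rep(1, n), w, type = "open")[(h + 1):(h + n)]
  num / mass
}

#' Wavelet modulus ratio
#'
#' The time- and scale-resolved synchrony index
#' \deqn{\rho(t,s) = \frac{G_s * |\sum_i w_i(\cdot,s)|}{G_s * \sum_i |w_i(\cdot,s)|}}
#' where `w_i` are the units' Morlet coefficients and `G_s` a Gaussian kernel
#' in time with standard deviation `s` (truncated at 4 sd, renormalized). The
#' numerator smooths the modulus of the coefficient sum (total abundance
#' variation at scale s), the denominator the sum of coefficient moduli (the
#' summed fluctuation amplitude of the individual units). The triangle
#' inequality bounds the ratio in \[0, 1\]: 1 means the units fluctuate in
#' phase (synchrony), values near 0 mean their fluctuations cancel
#' (compensation). Cells where the denominator is below machine tolerance, and
#' cells beyond the cone of influence, are `NA`.
#'
#' @param fields list of `wavelet_field`s on a common (time, scale) grid, or a
#'   numeric matrix / `abundance_matrix` (time x units) whose columns are
#'   transformed first.
#' @param scales scales passed to [morlet_cwt()] when `fields` is a matrix.
#' @param kernel_width_factor multiplier on the kernel standard deviation
#'   relative to the scale (default 1).
#' @param omega0 Morlet central frequency when transforming a matrix.
#' @return object of class `wmr_map`: list with `rho` (time x scale, `NA`
#'   outside the cone of influence), `scales`, `times`, `coi_scale`,
#'   `n_units`.
#' @export
wavelet_modulus_ratio <- function(fields, scales = NULL,
                                  kernel_width_factor = 1, omega0 = 6) {
  if (is.matrix(fields) || inherits(fields, "abundance_matrix")) {
    m <- unclass(as.matrix(fields))
    fields <- lapply(seq_len(ncol(m)),
                     function(j) morlet_cwt(m[, j], scales = scales, omega0 = omega0))
  }
  if (length(fields) < 1L) stop("need at least one wavelet field")
  ref <- fields[[1]]
  for (f in fields)
    if (!identical(f$scales, ref$scales) || !identical(f$times, ref$times))
      stop("wavelet fields must share a common (time, scale) grid")
  csum <- Reduce(`+`, lapply(fields, function(f) f$coef))
  msum <- Reduce(`+`, lapply(fields, function(f) Mod(f$coef)))
  n_t <- length(ref$times)
  rho <- matrix(NA_real_, n_t, length(ref$scales))
  sdf <- kernel_width_factor
  tolerance <- .Machine$double.eps^0.5
  for (j in seq_along(ref$scales)) {
    num <- gaussian_smooth(Mod(csum[, j]), ref$scales[j] * sdf)
    den <- gaussian_smooth(msum[, j], ref$scales[j] * sdf)
    r <- num / den
    r[den < tolerance * max(den, 1)] <- NA_real_
    rho[, j] <- r
  }
  # mask beyond the cone of influence
  coi <- outer(ref$coi_scale, ref$scales, `>=`)
  rho[!coi] <- NA_real_
  structure(list(rho = rho, scales = ref$scales, times = ref$times,
                 coi_scale = ref$coi_scale, n_units = length(fields)),
            class = "wmr_map")
}

#' @export
print.wmr_map <- function(x, ...) {
  ok <- !is.na(x$rho)
  cat(sprintf("Wavelet modulus ratio map: %d times x %d scales, %d units\n",
              length(x$times), length(x$scales), x$n_units))
  cat(sprintf("  unmasked cells: %d; rho range %.3f..%.3f\n",
              sum(ok), min(x$rho[ok]), max(x$rho[ok])))
  invisible(x)
}

#' Wavelet modulus ratio with pointwise surrogate significance
#'
#' Computes the observed modulus-ratio map, then `n_surrogates` replicates in
#' which every unit's monthly series is independently replaced by an IAAFT
#' surrogate (each unit keeps its value distribution and spectrum, but phase
#' relationships between units are randomized) and the map recomputed. A cell
#' is flagged `low` when the observed rho sits in the lower alpha/2 tail of
#' its surrogate distribution — one-sided count p-value
#' `(r + 1)/(n + 1) <= alpha/2`, i.e. below the alpha/2 empirical quantile —
#' indicating significant compensation, and `high` symmetrically in the upper
#' tail (significant synchrony);
#' significance is pointwise per cell, with no areawise correction, and never
#' reported inside the cone-of-influence mask.
#'
#' @param matrix `abundance_matrix` or numeric matrix (time x units), >= 2 units.
#' @param scales scales in months (default [default_scales()]).
#' @param n_surrogates surrogate replicates (default 1000).
#' @param alpha two-sided pointwise level (default 0.10).
#' @param seed integer seed; surrogate k uses stream `seed + k`.
#' @param omega0 Morlet central frequency.
#' @return list with `map` (the observed `wmr_map`) and `significance`
#'   (class `wmr_significance`): `low_mask`, `high_mask`, `alpha`,
#'   `n_surrogates`, `seed`, plus `frac_le`/`frac_ge`, the per-cell fractions
#'   of surrogates at or below / at or above the observed rho.
#' @export
wmr_significance <- function(matrix, scales = NULL, n_surrogates = 1000L,
                             alpha = 0.10, seed = NULL, omega0 = 6) {
  m <- unclass(as.matrix(matrix))
  if (ncol(m) < 2L) stop("significance testing needs at least 2 units")
  observed <- wavelet_modulus_ratio(m, scales = scales, omega0 = omega0)
  obs <- observed$rho
  n_le <- array(0L, dim(obs))
  n_ge <- array(0L, dim(obs))
  for (k in seq_len(n_surrogates)) {
    if (!is.null(seed)) set.seed(seed + k)
    surr <- apply(m, 2, iaaft_surrogate)
    rho_k <- wavelet_modulus_ratio(surr, scales = observed$scales,
                                   omega0 = omega0)$rho
    le <- rho_k <= obs; le[is.na(le)] <- FALSE
    ge <- rho_k >= obs; ge[is.na(ge)] <- FALSE
    n_le <- n_le + le
    n_ge <- n_ge + ge
  }
  ok <- !is.na(obs)
  # one-sided surrogate-count p-values per cell; the (r+1)/(n+1) floor means
  # a single surrogate can never reach alpha/2, and the two flags can never
  # both hold
  p_low <- (n_le + 1) / (n_surrogates + 1)
  p_high <- (n_ge + 1) / (n_surrogates + 1)
  low <- ok & (p_low <= alpha / 2)
  high <- ok & (p_high <= alpha / 2)
  low[!ok] <- FALSE; high[!ok] <- FALSE
  sig <- structure(list(low_mask = low, high_mask = high, alpha = alpha,
                        n_surrogates = n_surrogates, seed = seed,
                        frac_le = n_le / n_surrogates,
                        frac_ge = n_ge / n_surrogates),
                   class = "wmr_significance")
  list(map = observed, significance = sig)
}
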