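#' Configuration for the forced community simulator
#'
#' Bundles and validates the parameters of [simulate_forced_community()].
#' Defaults describe a stable two-guild community under moderate seasonal
#' forcing: Ricker-type density dependence (growth rate 0.5 at carrying
#' capacity 100, intraspecific competition 1, weak interspecific competition
#' 0.2) and an environmental driver `E(t) = sin(2*pi*t/12) + noise` entering
#' the log-scale growth with species response `beta`. Opposed `beta` signs
#' between the guilds produce compensatory dynamics; a common sign produces
#' community-wide synchrony. White monthly driver noise (sd 0.5) is what
#' carries interannual signal: seasonal averages of the deterministic
#' sinusoid are identical every year, so year-to-year covariation comes from
#' the shared driver anomalies.
#'
#' @param n_species_per_guild species per guild (default 10).
#' @param n_guilds 1 or 2 (default 2).
#' @param n_months series length in months (>= 64; default 420, i.e. 35 years).
#' @param r intrinsic growth rate (default 0.5).
#' @param K carrying capacity (default 100).
#' @param intra,inter intra-/interspecific competition coefficients
#'   (defaults 1 and 0.2).
#' @param beta magnitude of the environmental response; guild 1 responds
#'   `+beta`, guild 2 `sign_opposed ? -beta : +beta` (default 0.5).
#' @param sign_opposed if `TRUE` (default) the two guilds respond with
#'   opposite signs to the driver (compensatory regime); if `FALSE` both
#'   respond positively (synchronized regime).
#' @param driver_period driver oscillation period in months (default 12).
#' @param driver_noise_sd sd of white noise added to the driver (default 0.5).
#' @param sigma sd of species-specific demographic noise on the log scale
#'   (default 0.1).
#' @param round_counts round abundances to integers, with exact zeros below
#'   0.5, to emulate count data (default TRUE).
#' @param seed integer seed.
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_species_per_guild = 10L, n_guilds = 2L,
                              n_months = 420L, r = 0.5, K = 100,
                              intra = 1, inter = 0.2, beta = 0.5,
                              sign_opposed = TRUE, driver_period = 12,
                              driver_noise_sd = 0.5, sigma = 0.1,
                              round_counts = TRUE, seed = NULL) {
  if (n_months < 64L) stop("simulations need at least 64 months")
  if (!n_guilds %in% 1:2) stop("n_guilds must be 1 or 2")
  if (K <= 0) stop("carrying capacity must be positive")
  structure(as.list(environment()), class = "simulation_config")
}

#' Simulate a seasonally forced multispecies community
#'
#' Discrete-time Ricker/Lotka-Volterra dynamics with a shared environmental
#' driver on the log-scale growth:
#' \deqn{N_i(t+1) = N_i(t) \exp\big(r (1 - \textstyle\sum_j \alpha_{ij} N_j(t) / K)
#'   + \beta_i E(t) + \sigma \epsilon_{it}\big)}
#' with `E(t) = sin(2*pi*t/period) + driver noise` shared by all species,
#' `alpha_ii = intra`, `alpha_ij = inter`, and independent standard-normal
#' `epsilon`. Species start at the symmetric equilibrium
#' `K / (intra + (S-1) inter)` and the first 24 months are discarded as
#' burn-in. With opposed guild responses the guild totals move against each
#' other (compensation); with a common response all species covary.
#'
#' @param config a [simulation_config()].
#' @return an `abundance_matrix` (rounded to integer counts when
#'   `round_counts`), with units named `g<guild>_s<species>`, starting
#'   January of year 2000 by convention.
#' @export
simulate_forced_community <- function(config) {
  cf <- config
  if (!is.null(cf$seed)) set.seed(cf$seed)
  n_g <- cf$n_guilds
  S <- cf$n_species_per_guild * n_g
  guild <- rep(seq_len(n_g), each = cf$n_species_per_guild)
  beta_i <- cf$beta * if (n_g == 2L && cf$sign_opposed) c(1, -1)[guild] else rep(1, S)
  burn <- 24L
  total_t <- cf$n_months + burn
  alpha_row_sum <- function(N) cf$intra * N + cf$inter * (sum(N) - N)
  N <- rep(cf$K / (cf$intra + (S - 1) * cf$inter), S)
  out <- matrix(0, cf$n_months, S)
  drive <- sin(2 * pi * seq_len(total_t) / cf$driver_period) +
    stats::rnorm(total_t, sd = cf$driver_noise_sd)
  for (t in seq_len(total_t)) {
    growth <- cf$r * (1 - alpha_row_sum(N) / cf$K) +
      beta_i * drive[t] + stats::rnorm(S, sd = cf$sigma)
    N <- N * exp(growth)
    if (any(!is.finite(N)))
      stop("simulation diverged (non-finite abundance); parameters: r = ",
           cf$r, ", beta = ", cf$beta, ", sigma = ", cf$sigma)
    if (t > burn) out[t - burn, ] <- N
  }
  if (cf$round_counts) out <- round(out)
  colnames(out) <- sprintf("g%d_s%02d", guild, sequence(rep(cf$n_species_per_guild, n_g)))
  abundance_matrix(out, start = c(2000L, 1L))
}

#' Two antiphase sinusoidal units
#'
#' Unit 1 is `offset + a1 sin(2 pi t / period)`, unit 2 is
#' `offset - a2 sin(2 pi t / period)`, plus independent Gaussian noise. With
#' equal amplitudes and no noise the summed series is exactly constant — the
#' canonical perfect-compensation fixture; unequal amplitudes emulate
#' dominance (one unit's fluctuation cannot be offset by the other).
#'
#' @param n_months series length.
#' @param period oscillation period in months (>= 4).
#' @param a1,a2 amplitudes of the two units.
#' @param noise_sd sd of independent additive noise (default 0).
#' @param offset baseline level; default `max(a1, a2) + 5 * noise_sd + 1`,
#'   generous enough to keep values nonnegative.
#' @param seed integer seed for the noise.
#' @return an `abundance_matrix` with units `u1`, `u2`.
#' @export
make_antiphase_pair <- function(n_months, period = 12, a1 = 50, a2 = 50,
                                noise_sd = 0, offset = NULL, seed = NULL) {
  if (period < 4) stop("period must be at least 4 months")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(offset)) offset <- max(a1, a2) + 5 * noise_sd + 1
  t <- seq_len(n_months)
  s <- sin(2 * pi * t / period)
  vals <- cbind(u1 = offset + a1 * s + stats::rnorm(n_months, sd = noise_sd),
                u2 = offset - a2 * s + stats::rnorm(n_months, sd = noise_sd))
  if (any(vals < 0))
    stop("offset insufficient to keep abundances nonnegative")
  abundance_matrix(vals, start = c(2000L, 1L))
}

#' Independent autocorrelated units
#'
#' `n` mutually independent AR(1) series with unit-variance innovations,
#' shifted to a positive baseline. The null fixture for calibration: any
#' apparent synchrony among these units is a false positive.
#'
#' @param n_time series length (months or years, depending on use).
#' @param n number of units (>= 2).
#' @param ar_coefficient AR(1) coefficient, `|phi| < 1` (0 gives white noise).
#' @param shift positive baseline added to every series (default 10).
#' @param seed integer seed.
#' @return an `abundance_matrix`.
#' @export
make_independent <- function(n_time, n, ar_coefficient = 0, shift = 10,
                             seed = NULL) {
  if (n < 2L) stop("need at least 2 units")
  if (abs(ar_coefficient) >= 1) stop("|ar_coefficient| must be < 1")
  if (!is.null(seed)) set.seed(seed)
  vals <- vapply(seq_len(n), function(j) {
    e <- stats::rnorm(n_time)
    x <- if (ar_coefficient == 0) e
    else as.numeric(stats::filter(e, ar_coefficient, method = "recursive"))
    x + shift
  }, numeric(n_time))
  vals[vals < 0] <- 0
  colnames(vals) <- sprintf("u%02d", seq_len(n))
  abundance_matrix(vals, start = c(2000L, 1L))
}

#' Synchronous units around a shared seasonal latent series
#'
#' One latent seasonal series (baseline 10, annual sinusoid of amplitude 5,
#' plus latent white noise of sd 1) observed by every unit with small
#' independent observation noise — the positive-control fixture for synchrony.
#'
#' @param n_time series length in months.
#' @param n number of units (>= 2).
#' @param noise_sd sd of the per-unit independent noise (0 gives identical
#'   copies).
#' @param seed integer seed.
#' @return an `abundance_matrix`.
#' @export
make_synchronous <- function(n_time, n, noise_sd = 0.5, seed = NULL) {
  if (n < 2L) stop("need at least 2 units")
  if (!is.null(seed)) set.seed(seed)
  t <- seq_len(n_time)
  latent <- 10 + 5 * sin(2 * pi * t / 12) + stats::rnorm(n_time)
  vals <- vapply(seq_len(n),
                 function(j) latent + stats::rnorm(n_time, sd = noise_sd),
                 numeric(n_time))
  vals[vals < 0] <- 0
  colnames(vals) <- sprintf("u%02d", seq_len(n))
  abundance_matrix(vals, start = c(2000L, 1L))
}

#' Zero-inflate a matrix
#'
#' Sets each cell independently to exact 0 with probability `p_zero`,
#' emulating the exact zeros that monthly snapshots of rare species produce.
#'
#' @param matrix an `abundance_matrix`.
#' @param p_zero zeroing probability in \[0, 1).
#' @param seed integer seed.
#' @return an `abundance_matrix`.
#' @export
apply_zero_inflation <- function(matrix, p_zero, seed = NULL) {
  if (p_zero < 0 || p_zero >= 1) stop("p_zero must be in [0, 1)")
  if (p_zero == 0) return(matrix)
  if (!is.null(seed)) set.seed(seed)
  vals <- unclass(matrix)
  vals[stats::runif(length(vals)) < p_zero] <- 0
  tm <- time_index(matrix)
  abundance_matrix(vals, start = c(tm$year[1], tm$month[1]))
}

#' Skew the species-abundance distribution
#'
#' Multiplies each unit by an independent lognormal factor, applied either to
#' the unit's whole series (`mode = "mean"`: skews mean abundances) or to its
#' deviations from its own temporal mean (`mode = "amplitude"`: skews the
#' amplitude of temporal variation while keeping mean levels). Deviation
#' scaling clips at zero to preserve nonnegativity.
#'
#' @param matrix an `abundance_matrix`.
#' @param lognormal_sd sd of the lognormal log-factor (0 is the identity).
#' @param mode `"mean"` or `"amplitude"`.
#' @param seed integer seed.
#' @return an `abundance_matrix`.
#' @export
apply_abundance_skew <- function(matrix, lognormal_sd,
                                 mode = c("mean", "amplitude"), seed = NULL) {
  mode <- match.arg(mode)
  if (lognormal_sd == 0) return(matrix)
  if (!is.null(seed)) set.seed(seed)
  vals <- unclass(matrix)
  f <- exp(stats::rnorm(ncol(vals), sd = lognormal_sd))
  if (mode == "mean") {
    vals <- sweep(vals, 2, f, `*`)
  } else {
    mu <- colMeans(vals)
    vals <- sweep(sweep(vals, 2, mu, `-`), 2, f, `*`)
    vals <- sweep(vals, 2, mu, `+`)
    vals[vals < 0] <- 0
  }
  tm <- time_index(matrix)
  abundance_matrix(vals, start = c(tm$year[1], tm$month[1]))
}
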