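#' Toroidal-shift surrogate
#'
#' Circularly shifts each series by an independent uniform random lag in
#' `{0, ..., T-1}`: the value at position t moves to t + lag, wrapping past
#' the end back to the beginning. Each unit's value multiset and circular
#' autocorrelation are preserved exactly, while cross-correlations between
#' units are destroyed — the within-guild null model for the synchrony index.
#'
#' @param x numeric vector, or matrix with time in rows (each column gets an
#'   independent lag).
#' @param lags optional integer lag(s), one per series, for deterministic use;
#'   by default drawn uniformly from `0:(T-1)`.
#' @return an object of the same shape as `x`.
#' @export
toroidal_shift <- function(x, lags = NULL) {
  if (is.matrix(x)) {
    n <- nrow(x)
    if (n < 2L) stop("series too short to shift")
    if (is.null(lags)) lags <- sample.int(n, ncol(x), replace = TRUE) - 1L
    out <- x
    for (j in seq_len(ncol(x)))
      out[, j] <- x[shift_index(n, lags[j]), j]
    return(out)
  }
  n <- length(x)
  if (n < 2L) stop("series too short to shift")
  if (is.null(lags)) lags <- sample.int(n, 1L) - 1L
  x[shift_index(n, lags[1])]
}

# index so that out[t] = x[t - lag] (value at t moves to t + lag, wrapping)
shift_index <- function(n, lag) (seq_len(n) - 1L - lag) %% n + 1L

#' Iterative amplitude-adjusted Fourier transform surrogate
#'
#' Generates a randomized series that keeps the original's value distribution
#' exactly (the surrogate is a permutation of the data) and its power spectrum
#' approximately, while scrambling the phase relationships that carry
#' cross-correlation — the null model for between-guild synchrony and for the
#' wavelet modulus ratio.
#'
#' Starting from a random permutation, the algorithm alternates (a) replacing
#' the Fourier amplitudes of the current iterate with the original's, keeping
#' the current phases (the DC component is the original's, and for even
#' lengths the Nyquist bin stays real), and (b) rank-remapping the values onto
#' the original's sorted values with stable first-occurrence tie handling. It
#' stops when the rank ordering no longer changes or after `max_iter`
#' iterations, whichever comes first.
#'
#' @param x numeric vector, length >= 8, non-constant.
#' @param max_iter maximum number of iterations (default 100).
#' @param tol relative spectral-mismatch tolerance recorded for the
#'   convergence flag (default 1e-8).
#' @return a numeric vector, a permutation of `x`, with attributes
#'   `converged` (logical) and `iterations`.
#' @references Schreiber & Schmitz-style amplitude-adjusted surrogates.
#' @export
iaaft_surrogate <- function(x, max_iter = 100L, tol = 1e-8) {
  n <- length(x)
  if (n < 8L) stop("IAAFT needs at least 8 points")
  if (stats::var(x) == 0) stop("IAAFT is undefined for a constant series")
  if (mean(x == 0) > 0.5)
    warning("more than 50% exact zeros: surrogate spectrum may converge slowly")
  sorted_x <- sort(x)
  target_amp <- Mod(stats::fft(x))
  s <- x[sample.int(n)]
  prev_rank <- integer(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    f <- stats::fft(s)
    mod <- Mod(f)
    phase <- ifelse(mod == 0, 1 + 0i, f / mod)
    s2 <- Re(stats::fft(target_amp * phase, inverse = TRUE)) / n
    rk <- rank(s2, ties.method = "first")
    s <- sorted_x[rk]
    if (identical(rk, prev_rank)) { converged <- TRUE; break }
    prev_rank <- rk
    if (iter >= max_iter) break
  }
  if (!converged) {
    mismatch <- spectral_mismatch(s, target_amp)
    converged <- mismatch < tol
    if (!converged)
      warning(sprintf("IAAFT did not converge in %d iterations (mismatch %.3g)",
                      max_iter, mismatch))
  }
  structure(s, converged = converged, iterations = iter)
}

spectral_mismatch <- function(s, target_amp) {
  a <- Mod(stats::fft(s))
  sum((a - target_amp)^2) / sum(target_amp^2)
}

#' Null distribution of a statistic under a surrogate scheme
#'
#' Applies a surrogate method independently to every unit of a matrix
#' `n_surrogates` times and evaluates `stat_fn` on each randomized replicate.
#' Within-guild synchrony uses `"toroidal_shift"`; two-group comparisons and
#' all wavelet nulls use `"iaaft"`.
#'
#' @param stat_fn function taking a matrix (time x units) and returning a
#'   numeric scalar (or vector, in which case `stats` is a matrix with one row
#'   per surrogate).
#' @param data numeric matrix, time in rows.
#' @param method `"toroidal_shift"` or `"iaaft"`.
#' @param n_surrogates number of surrogate replicates (default 1000).
#' @param seed integer seed; the k-th surrogate uses the stream derived from
#'   `seed + k`, so ensembles are reproducible and extendable.
#' @return object of class `surrogate_ensemble`: list with `method`,
#'   `n_surrogates`, `seed`, and `stats`.
#' @export
null_distribution <- function(stat_fn, data, method = c("toroidal_shift", "iaaft"),
                              n_surrogates = 1000L, seed = NULL) {
  method <- match.arg(method)
  data <- as.matrix(data)
  surrogate_fn <- switch(method,
    toroidal_shift = function(m) toroidal_shift(m),
    iaaft = function(m) apply(m, 2, iaaft_surrogate))
  one <- function(k) {
    if (!is.null(seed)) set.seed(seed + k)
    val <- tryCatch(stat_fn(surrogate_fn(data)), error = function(e)
      stop("statistic failed on surrogate ", k, ": ", conditionMessage(e)))
    val
  }
  stats <- vapply(seq_len(n_surrogates), one,
                  FUN.VALUE = one_shape(stat_fn, data))
  if (is.matrix(stats)) stats <- t(stats)
  structure(list(method = method, n_surrogates = n_surrogates,
                 seed = seed, stats = stats),
            class = "surrogate_ensemble")
}

one_shape <- function(stat_fn, data) {
  # evaluate once on the observed data only to learn the output shape
  v <- stat_fn(data)
  numeric(length(v))
}

#' Surrogate p-value
#'
#' The standard surrogate-count p-value `(r + 1) / (n + 1)`, where r is the
#' number of surrogate statistics at least as extreme as the observed value
#' (ties count as extreme) and n the ensemble size. Its smallest attainable
#' value is `1 / (n + 1)`. Two-sided p-values combine the two one-sided values
#' as `min(1, 2 * min(p_greater, p_less))`, the conservative standard for
#' surrogate tests; both one-sided values are returned so either convention
#' can be reported.
#'
#' @param observed observed statistic.
#' @param ensemble a `surrogate_ensemble` (with scalar `stats`) or a numeric
#'   vector of null statistics.
#' @param alternative `"greater"`, `"less"`, or `"two_sided"`.
#' @return object of class `surrogate_test`: list with `observed`, `p_value`,
#'   `alternative`, `p_greater`, `p_less`, and `n_surrogates`.
#' @export
surrogate_p_value <- function(observed, ensemble,
                              alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stats <- if (inherits(ensemble, "surrogate_ensemble")) ensemble$stats else ensemble
  n <- length(stats)
  if (n == 0L) stop("empty surrogate ensemble")
  p_greater <- (sum(stats >= observed) + 1) / (n + 1)
  p_less <- (sum(stats <= observed) + 1) / (n + 1)
  p <- switch(alternative,
              greater = p_greater,
              less = p_less,
              two_sided = min(1, 2 * min(p_greater, p_less)))
  structure(list(observed = observed, p_value = p, alternative = alternative,
                 p_greater = p_greater, p_less = p_less, n_surrogates = n),
            class = "surrogate_test")
}

#' @export
print.surrogate_test <- function(x, ...) {
  cat(sprintf("observed = %.4f, p = %.4g (%s, %d surrogates)\n",
              x$observed, x$p_value, x$alternative, x$n_surrogates))
  invisible(x)
}

#' Benjamini-Hochberg correction over a family of tests
#'
#' Step-up false-discovery-rate control. In the year-to-year track the family
#' is the 6 tests per grouping scheme (2 seasons x 3 periods), which share
#' partially overlapping data.
#'
#' @param p_values numeric vector of raw p-values in (0, 1].
#' @param q target false discovery rate (default 0.10).
#' @return list with `adjusted` (BH-adjusted p-values) and `reject` (logical).
#' @export
bh_adjust <- function(p_values, q = 0.10) {
  if (any(p_values <= 0 | p_values > 1)) stop("p-values must lie in (0, 1]")
  adjusted <- stats::p.adjust(p_values, method = "BH")
  list(adjusted = adjusted, reject = adjusted <= q)
}
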