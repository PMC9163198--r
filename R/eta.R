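#' Year-to-year community synchrony index
#'
#' Computes the synchrony index of Gross et al.: the mean, over species i, of
#' the Pearson correlation between species i's yearly abundance and the summed
#' yearly abundance of all other species,
#' \deqn{\eta = \frac{1}{n} \sum_i \mathrm{Corr}(X_i, \sum_{j \ne i} X_j).}
#' The index lies in \[-1, 1\]: -1 is perfect compensation (total abundance
#' constant), +1 complete synchrony, and 0 the average for independently
#' fluctuating populations. Unlike variance-ratio statistics it does not
#' depend on community richness, which makes values comparable across
#' taxonomic scales.
#'
#' Units with zero temporal variance (e.g. species absent from a season in
#' every year) have no defined correlation; they are excluded from the average
#' and reported in `dropped_units` rather than imputed. Because a constant
#' unit adds a constant to every "rest of community" sum, dropping it leaves
#' the remaining correlations unchanged.
#'
#' @param series a `seasonal_series`, or any numeric matrix with years in rows
#'   and units in columns.
#' @param impute_zero if `TRUE`, zero-variance units contribute a correlation
#'   of 0 to the average instead of being dropped (sensitivity analyses only).
#' @return an object of class `eta_result`: a list with `eta`, `n_units`
#'   (units entering the average), `n_years`, `season`, `period`,
#'   `dropped_units`, and `correlations` (the per-unit terms).
#' @seealso [eta_between()] for the two-group case.
#' @export
synchrony_eta <- function(series, impute_zero = FALSE) {
  Y <- unclass(as.matrix(series))
  if (nrow(Y) < 3L) stop("eta needs at least 3 years")
  v <- apply(Y, 2, stats::var)
  variable <- v > 0
  if (sum(variable) < 2L) stop("eta needs at least 2 units with temporal variance")
  dropped <- colnames(Y)[!variable]
  Z <- Y[, variable, drop = FALSE]
  tot <- rowSums(Z)
  r <- vapply(seq_len(ncol(Z)),
              function(i) stats::cor(Z[, i], tot - Z[, i]), numeric(1))
  names(r) <- colnames(Z)
  undef <- is.na(r)  # rest-of-community sum constant
  if (any(undef)) {
    dropped <- c(dropped, colnames(Z)[undef])
    r <- r[!undef]
    if (length(r) == 0L) stop("no unit has a defined correlation with the rest")
  }
  eta <- if (impute_zero && ncol(Y) > length(r))
    sum(r) / ncol(Y) else mean(r)
  structure(list(eta = eta, n_units = length(r), n_years = nrow(Y),
                 season = attr(series, "season") %||% NA_character_,
                 period = attr(series, "period") %||% NA_character_,
                 dropped_units = dropped, correlations = r),
            class = "eta_result")
}

#' Synchrony between two (summed) groups
#'
#' With exactly two units every cross-term of the synchrony index is the same
#' correlation, so the index reduces to the plain Pearson correlation between
#' the two group-level series.
#'
#' @param group_a,group_b numeric vectors of yearly values over the same years.
#' @return an `eta_result` with `n_units = 2`.
#' @export
eta_between <- function(group_a, group_b) {
  if (length(group_a) != length(group_b)) stop("series must cover the same years")
  if (length(group_a) < 3L) stop("eta needs at least 3 years")
  if (stats::var(group_a) == 0 || stats::var(group_b) == 0)
    stop("constant group series: correlation undefined")
  r <- stats::cor(group_a, group_b)
  structure(list(eta = r, n_units = 2L, n_years = length(group_a),
                 season = NA_character_, period = NA_character_,
                 dropped_units = character(0),
                 correlations = c(a = r, b = r)),
            class = "eta_result")
}

#' @export
print.eta_result <- function(x, ...) {
  cat(sprintf("eta = %.4f  (n_units = %d, n_years = %d)\n",
              x$eta, x$n_units, x$n_years))
  if (length(x$dropped_units))
    cat("  dropped (zero variance):", paste(x$dropped_units, collapse = ", "), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# fast eta on a plain matrix, no validation or bookkeeping: used in surrogate
# loops where it is called hundreds of thousands of times
eta_value <- function(Y) {
  tot <- rowSums(Y)
  mean(vapply(seq_len(ncol(Y)),
              function(i) stats::cor(Y[, i], tot - Y[, i]), numeric(1)))
}
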