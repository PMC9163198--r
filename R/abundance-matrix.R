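#' Monthly community abundance matrix
#'
#' The central data object of the package: a numeric matrix with one row per
#' calendar month (contiguous, no gaps) and one column per unit (species or
#' group). Absences are exact zeros, never `NA` — in sustained monitoring
#' schemes a missing count is interpreted as a true absence. Row names are
#' ISO year-months (`"1981-01"`).
#'
#' @param values numeric matrix (months x units), all values >= 0.
#' @param start length-2 integer vector `c(year, month)` of the first row.
#' @param units optional character vector of unit labels; defaults to the
#'   column names of `values`.
#' @return an object of class `abundance_matrix`.
#' @export
abundance_matrix <- function(values, start, units = colnames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("`values` must be numeric")
  if (anyNA(values)) stop("abundance matrices have no missing cells; use exact zeros")
  if (any(values < 0)) stop("abundances must be nonnegative")
  if (length(start) != 2L || start[2] < 1L || start[2] > 12L)
    stop("`start` must be c(year, month) with month in 1..12")
  if (is.null(units)) units <- paste0("u", seq_len(ncol(values)))
  tm <- month_sequence(start, nrow(values))
  dimnames(values) <- list(format_ym(tm$year, tm$month), units)
  structure(values, class = c("abundance_matrix", class(matrix())))
}

#' @export
print.abundance_matrix <- function(x, ...) {
  tm <- time_index(x)
  cat(sprintf("Monthly abundance matrix: %d months (%s to %s), %d units\n",
              nrow(x), rownames(x)[1], rownames(x)[nrow(x)], ncol(x)))
  cat(sprintf("  total abundance %.6g; zero cells %.1f%%\n",
              sum(x), 100 * mean(x == 0)))
  invisible(x)
}

# (year, month) pairs for n consecutive months from `start`
month_sequence <- function(start, n) {
  k <- (start[1] * 12L + (start[2] - 1L)) + seq_len(n) - 1L
  list(year = k %/% 12L, month = k %% 12L + 1L)
}

format_ym <- function(year, month) sprintf("%04d-%02d", year, month)

#' Year and month index of an abundance matrix
#'
#' @param x an `abundance_matrix`.
#' @return a list with integer vectors `year` and `month`, one entry per row.
#' @export
time_index <- function(x) {
  ym <- rownames(x)
  list(year = as.integer(substr(ym, 1, 4)), month = as.integer(substr(ym, 6, 7)))
}

#' Seasonal series of yearly mean abundances
#'
#' A matrix of seasonal mean abundances with one row per season-year and one
#' column per unit, carrying the season (`"warm"` or `"cold"`) and the period
#' label (`"all"`, `"pre"`, `"post"`) as attributes.
#'
#' @param values numeric matrix (years x units), nonnegative.
#' @param years integer vector of season-years (row labels).
#' @param season `"warm"` or `"cold"`.
#' @param period period label, default `"all"`.
#' @return an object of class `seasonal_series`.
#' @export
seasonal_series <- function(values, years, season, period = "all") {
  values <- as.matrix(values)
  season <- match.arg(season, c("warm", "cold"))
  rownames(values) <- as.character(years)
  structure(values, season = season, period = period,
            class = c("seasonal_series", class(matrix())))
}

#' @export
print.seasonal_series <- function(x, ...) {
  cat(sprintf("Seasonal series (%s season, period %s): %d years, %d units\n",
              attr(x, "season"), attr(x, "period"), nrow(x), ncol(x)))
  invisible(x)
}

season_years <- function(x) as.integer(rownames(x))

#' Write an abundance matrix or seasonal series to delimited text
#'
#' Writes a tab-separated table with the time label (ISO year-month, or year)
#' in the first column and one column per unit.
#'
#' @param x an `abundance_matrix` or `seasonal_series`.
#' @param path output file path.
#' @export
write_abundance_matrix <- function(x, path) {
  df <- data.frame(time = rownames(x), as.data.frame(unclass(x)[, , drop = FALSE]),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
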