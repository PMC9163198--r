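#' Read long-format count records
#'
#' Reads delimited text (comma or tab, auto-detected from the header line)
#' with columns `year`, `month`, `species`, `count`. Multiple records per
#' (year, month, species) are allowed; [build_monthly_matrix()] reduces them
#' by the monthly maximum.
#'
#' @param path path to a delimited text file with a header.
#' @return a data.frame with columns year, month, species, count.
#' @export
read_count_records <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("year", "month", "species", "count")
  if (!all(need %in% names(df)))
    stop("count records need columns: ", paste(need, collapse = ", "))
  validate_records(df[need])
}

validate_records <- function(df) {
  if (any(df$count < 0)) stop("negative counts are not valid abundances")
  if (any(df$month < 1 | df$month > 12)) stop("month must be in 1..12")
  df
}

#' Write count records in the long format the package reads
#'
#' @param records data.frame with columns year, month, species, count.
#' @param path output path; tab-separated with header.
#' @export
write_count_records <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert an abundance matrix to long-format count records
#'
#' @param matrix an `abundance_matrix`.
#' @return data.frame with columns year, month, species, count (all cells,
#'   including zeros).
#' @export
as_count_records <- function(matrix) {
  tm <- time_index(matrix)
  data.frame(year = rep(tm$year, ncol(matrix)),
             month = rep(tm$month, ncol(matrix)),
             species = rep(colnames(matrix), each = nrow(matrix)),
             count = as.vector(unclass(matrix)))
}

#' Build the monthly community matrix from raw count records
#'
#' Reduces raw records to a complete months x species grid: each cell is the
#' maximum count observed for that species in that month (a monthly snapshot),
#' and species-months with no record are exact zeros. The grid always covers
#' the full requested time range and species universe.
#'
#' @param records data.frame with columns year, month, species, count.
#' @param species_universe ordered character vector of species labels to keep
#'   (records for other species are ignored).
#' @param time_range list with `start = c(year, month)` and `end = c(year, month)`.
#' @return an `abundance_matrix`.
#' @export
build_monthly_matrix <- function(records, species_universe, time_range) {
  validate_records(records)
  if (length(species_universe) == 0L) stop("species universe must be nonempty")
  start <- time_range$start; end <- time_range$end
  n <- (end[1] - start[1]) * 12L + (end[2] - start[2]) + 1L
  if (n < 1L) stop("time range must span at least one month")
  vals <- matrix(0, n, length(species_universe),
                 dimnames = list(NULL, species_universe))
  keep <- records$species %in% species_universe
  if (any(keep)) {
    rec <- records[keep, , drop = FALSE]
    row <- (rec$year - start[1]) * 12L + (rec$month - start[2]) + 1L
    ok <- row >= 1L & row <= n
    rec <- rec[ok, , drop = FALSE]; row <- row[ok]
    col <- match(rec$species, species_universe)
    # repeated records per cell reduce by max: assign in increasing count
    # order so the largest record wins
    ord <- order(rec$count)
    vals[cbind(row[ord], col[ord])] <- rec$count[ord]
  }
  abundance_matrix(vals, start = start)
}

#' Keep the k most frequent units
#'
#' Frequency is the number of months with a nonzero abundance; ties are broken
#' by total summed abundance, then by label order, which makes the selection
#' deterministic.
#'
#' @param matrix an `abundance_matrix`.
#' @param k number of units to retain (`k <=` number of units).
#' @return the `abundance_matrix` restricted to the selected units, in their
#'   original column order.
#' @export
select_frequent <- function(matrix, k) {
  if (k > ncol(matrix)) stop("k exceeds the number of units")
  occ <- colSums(matrix > 0)
  tot <- colSums(matrix)
  ord <- order(-occ, -tot, colnames(matrix))
  keep <- sort(ord[seq_len(k)])
  matrix[, keep, drop = FALSE]
}

#' Read a species-to-group mapping
#'
#' Two-column delimited text (species, group); species absent from the mapping
#' are excluded when the scheme is applied.
#'
#' @param path path to the mapping file (header required).
#' @return named character vector: `mapping[species] == group`.
#' @export
read_group_scheme <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, encoding = "UTF-8")
  stats::setNames(as.character(df[[2]]), df[[1]])
}

#' Sum species into groups
#'
#' Produces one unit per group whose monthly value is the sum over member
#' species; species not present in the mapping are dropped. Guild-level
#' series are built this way before seasonal averaging, so seasonal means of
#' a guild equal sums of the member species' seasonal means (linearity).
#'
#' @param matrix an `abundance_matrix`.
#' @param scheme named character vector mapping species label -> group label.
#' @return an `abundance_matrix` with one column per group (alphabetical).
#' @export
group_sum <- function(matrix, scheme) {
  mapped <- intersect(colnames(matrix), names(scheme))
  if (length(mapped) == 0L) stop("grouping scheme maps no unit present in the matrix")
  groups <- sort(unique(unname(scheme[mapped])))
  vals <- vapply(groups, function(g) {
    members <- mapped[scheme[mapped] == g]
    rowSums(matrix[, members, drop = FALSE])
  }, numeric(nrow(matrix)))
  tm <- time_index(matrix)
  abundance_matrix(vals, start = c(tm$year[1], tm$month[1]), units = groups)
}

# months belonging to each season-year; cold season of year y spans the
# year boundary (Nov y .. Feb y+1) and is labelled by the November year
season_months <- function(season) {
  if (season == "warm") list(months = 5:8, year_offset = c(0L, 0L, 0L, 0L))
  else list(months = c(11L, 12L, 1L, 2L), year_offset = c(0L, 0L, 1L, 1L))
}

#' Seasonal mean abundances
#'
#' Averages monthly abundances over the four months of a season for each year:
#' warm = May to August; cold = November and December of year y plus January
#' and February of year y+1, labelled with year y. Season-years with fewer
#' than four months inside the matrix (series edges) are dropped so that
#' seasonal means stay comparable across years.
#'
#' @param matrix an `abundance_matrix`.
#' @param season `"warm"` or `"cold"`.
#' @return a `seasonal_series` (years x units).
#' @export
seasonal_mean <- function(matrix, season = c("warm", "cold")) {
  season <- match.arg(season)
  sm <- season_months(season)
  tm <- time_index(matrix)
  key <- paste(tm$year, tm$month)
  years <- sort(unique(tm$year))
  rows <- lapply(years, function(y) {
    want <- paste(y + sm$year_offset, sm$months)
    idx <- match(want, key)
    if (anyNA(idx)) NULL else colMeans(matrix[idx, , drop = FALSE])
  })
  ok <- !vapply(rows, is.null, logical(1))
  if (!any(ok)) stop("no complete ", season, " season in the matrix range")
  seasonal_series(do.call(rbind, rows[ok]), years[ok], season)
}

#' Split a seasonal series at a cut year
#'
#' The cut is half-open: season-years strictly before `cut_year` form the
#' "pre" period, season-years at or after it the "post" period. An empty side
#' is returned with zero rows and a warning.
#'
#' @param series a `seasonal_series`.
#' @param cut_year integer cut year (default 2006, the management change).
#' @return list with elements `pre` and `post`, both `seasonal_series`.
#' @export
split_period <- function(series, cut_year = 2006L) {
  yrs <- season_years(series)
  pre <- yrs < cut_year
  if (all(pre) || !any(pre))
    warning("all season-years fall on one side of the cut year")
  mk <- function(sel, label)
    seasonal_series(series[sel, , drop = FALSE], yrs[sel],
                    attr(series, "season"), period = label)
  list(pre = mk(pre, "pre"), post = mk(!pre, "post"))
}

#' Read a body-mass table
#'
#' Two-column delimited text (species, mass_g) with positive masses in grams.
#'
#' @param path path to the table (header required).
#' @return named numeric vector of masses.
#' @export
read_body_mass_table <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, encoding = "UTF-8")
  masses <- stats::setNames(as.numeric(df[[2]]), df[[1]])
  if (any(masses <= 0)) stop("body masses must be positive")
  masses
}

#' Convert counts to biomass
#'
#' Multiplies every cell by the species' mean body mass so downstream indices
#' weight species by biomass rather than by individuals.
#'
#' @param matrix an `abundance_matrix` of counts.
#' @param masses named numeric vector, species label -> mean body mass (g).
#' @return an `abundance_matrix` in grams.
#' @export
to_biomass <- function(matrix, masses) {
  missing <- setdiff(colnames(matrix), names(masses))
  if (length(missing))
    stop("no body mass for species: ", paste(missing, collapse = ", "))
  out <- sweep(unclass(matrix), 2, masses[colnames(matrix)], `*`)
  tm <- time_index(matrix)
  abundance_matrix(out, start = c(tm$year[1], tm$month[1]))
}
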