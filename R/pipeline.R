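#' Analysis configuration
#'
#' Bundles everything the two analysis tracks need: the data source, the
#' grouping scheme, the run matrix (seasons x periods), surrogate settings and
#' output location. The data source is one of a path to long-format count
#' records, an `abundance_matrix` built programmatically, or a
#' [simulation_config()] to generate data in place.
#'
#' @param input path to a delimited count-record file, or an
#'   `abundance_matrix`.
#' @param simulate a [simulation_config()], used when `input` is `NULL`.
#' @param scheme path to a species-to-group mapping file, or a named character
#'   vector (species -> group); `NULL` runs community-level analyses only.
#' @param seasons seasons to analyse (subset of `c("warm", "cold")`).
#' @param cut_year period cut (default 2006); periods are `all`, `pre`
#'   (years < cut) and `post` (years >= cut).
#' @param n_frequent if not `NULL`, keep only the `n_frequent` most frequent
#'   species (applied after the matrix is built over the full time range).
#' @param n_surrogates surrogates per test (default 1000).
#' @param alpha significance level (default 0.10).
#' @param q false-discovery rate for the BH family (default `alpha`).
#' @param seed root seed; every surrogate stream derives from it.
#' @param scales wavelet scales in months (default [default_scales()]).
#' @param omega0 Morlet central frequency (default 6).
#' @param out_dir output directory; `NULL` skips file output.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(input = NULL, simulate = NULL, scheme = NULL,
                            seasons = c("warm", "cold"), cut_year = 2006L,
                            n_frequent = NULL, n_surrogates = 1000L,
                            alpha = 0.10, q = alpha, seed = 1L,
                            scales = NULL, omega0 = 6, out_dir = NULL) {
  if (is.null(input) && is.null(simulate))
    stop("provide either `input` data or a `simulate` configuration")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (n_surrogates < 1L) stop("n_surrogates must be >= 1")
  seasons <- match.arg(seasons, c("warm", "cold"), several.ok = TRUE)
  structure(as.list(environment()), class = "analysis_config")
}

#' Read an analysis configuration from a YAML file
#'
#' Field names match the arguments of [analysis_config()]; a `simulate` block
#' is passed to [simulation_config()].
#'
#' @param path YAML file path.
#' @return an `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) y$simulate <- do.call(simulation_config, y$simulate)
  do.call(analysis_config, y)
}

# resolve the configured data source into an abundance matrix + scheme
resolve_input <- function(config) {
  m <- config$input
  if (is.null(m)) m <- simulate_forced_community(config$simulate)
  if (is.character(m)) {
    records <- read_count_records(m)
    universe <- sort(unique(records$species))
    tr <- list(start = c(min(records$year), min(records$month[records$year == min(records$year)])),
               end = c(max(records$year), max(records$month[records$year == max(records$year)])))
    m <- build_monthly_matrix(records, universe, tr)
  }
  if (!is.null(config$n_frequent)) m <- select_frequent(m, config$n_frequent)
  scheme <- config$scheme
  if (is.character(scheme) && length(scheme) == 1L && is.null(names(scheme)) &&
      file.exists(scheme))
    scheme <- read_group_scheme(scheme)
  list(matrix = m, scheme = scheme)
}

# the three period slices of a seasonal series
period_slices <- function(series, cut_year) {
  halves <- suppressWarnings(split_period(series, cut_year))
  all <- series; attr(all, "period") <- "all"
  list(all = all, pre = halves$pre, post = halves$post)
}

eta_stage <- function(expr, grouping, season, period) {
  tryCatch(expr, error = function(e)
    stop(sprintf("eta track failed at %s / %s / %s: %s",
                 grouping, season, period, conditionMessage(e)), call. = FALSE))
}

#' Run the year-to-year synchrony track
#'
#' For every grouping level — the whole community at species level, the
#' species within each group, and (when the scheme has exactly two groups)
#' the pair of summed groups — computes the synchrony index per season and
#' period, its surrogate p-value (toroidal-shift null within communities and
#' groups; IAAFT null for the two-group comparison, where circular shifts of
#' only two series can leave spurious cross-correlation), and BH rejection
#' flags over the season-by-period family within each grouping.
#'
#' Period slices too short to test (fewer than 3 years, or fewer than 8 for
#' the IAAFT null) are reported with `NA` p-values.
#'
#' @param config an [analysis_config()].
#' @return data.frame with one row per (grouping, season, period): `eta`,
#'   `n_units`, `n_years`, `p_greater`, `p_less`, `p_two_sided`,
#'   `p_adjusted`, `bh_reject`. Written to `results.tsv` (plus
#'   `run_meta.json`) when `out_dir` is set.
#' @export
run_eta_track <- function(config) {
  inp <- resolve_input(config)
  m <- inp$matrix
  scheme <- inp$scheme
  groupings <- list(community = colnames(m))
  if (!is.null(scheme)) {
    present <- intersect(colnames(m), names(scheme))
    for (g in sort(unique(unname(scheme[present]))))
      groupings[[paste0("within_", g)]] <- present[scheme[present] == g]
    if (length(unique(unname(scheme[present]))) == 2L)
      groupings[["between"]] <- NA  # marker: summed two-group comparison
  }
  sums <- if (!is.null(scheme)) group_sum(m, scheme) else NULL
  rows <- list()
  for (gname in names(groupings)) {
    between <- gname == "between"
    src <- if (between) sums else m[, groupings[[gname]], drop = FALSE]
    for (season in config$seasons) {
      series <- seasonal_mean(src, season)
      slices <- period_slices(series, config$cut_year)
      for (pname in names(slices)) {
        rows[[length(rows) + 1L]] <- eta_stage(
          eta_one_cell(slices[[pname]], between, gname, season, pname, config),
          gname, season, pname)
      }
    }
  }
  res <- do.call(rbind, rows)
  # BH family: seasons x periods within each grouping
  res$p_adjusted <- NA_real_
  res$bh_reject <- NA
  for (gname in unique(res$grouping)) {
    idx <- which(res$grouping == gname & !is.na(res$p_two_sided))
    if (length(idx)) {
      adj <- bh_adjust(res$p_two_sided[idx], q = config$q)
      res$p_adjusted[idx] <- adj$adjusted
      res$bh_reject[idx] <- adj$reject
    }
  }
  if (!is.null(config$out_dir)) write_eta_outputs(res, config)
  res
}

eta_one_cell <- function(slice, between, gname, season, pname, config) {
  Y <- unclass(as.matrix(slice))
  base <- data.frame(grouping = gname, season = season, period = pname,
                     eta = NA_real_, n_units = NA_integer_,
                     n_years = nrow(Y), p_greater = NA_real_,
                     p_less = NA_real_, p_two_sided = NA_real_,
                     stringsAsFactors = FALSE)
  min_years <- if (between) 8L else 3L  # IAAFT needs length >= 8
  if (nrow(Y) < min_years) return(base)
  if (between) {
    obs <- eta_between(Y[, 1], Y[, 2])
  } else {
    variable <- apply(Y, 2, stats::var) > 0
    if (sum(variable) < 2L) return(base)
    obs <- synchrony_eta(slice)
    Y <- Y[, variable, drop = FALSE]
  }
  method <- if (between) "iaaft" else "toroidal_shift"
  ens <- null_distribution(eta_value, Y, method = method,
                           n_surrogates = config$n_surrogates,
                           seed = config$seed + cell_seed_offset(gname, season, pname))
  test <- surrogate_p_value(obs$eta, ens, "two_sided")
  base$eta <- obs$eta
  base$n_units <- obs$n_units
  base$p_greater <- test$p_greater
  base$p_less <- test$p_less
  base$p_two_sided <- test$p_value
  base
}

# deterministic per-cell seed offset so cells get independent surrogate streams
cell_seed_offset <- function(gname, season, pname) {
  key <- paste(gname, season, pname)
  # small stable hash of the key
  sum(utf8ToInt(key) * seq_along(utf8ToInt(key))) %% 10000L * 1000L
}

write_eta_outputs <- function(res, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(res, file.path(config$out_dir, "results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(track = "eta", seasons = config$seasons,
               cut_year = config$cut_year, n_surrogates = config$n_surrogates,
               alpha = config$alpha, q = config$q, seed = config$seed)
  jsonlite::write_json(meta, file.path(config$out_dir, "run_meta.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}

#' Run the wavelet synchrony track
#'
#' For the whole community and for each configured group with at least two
#' member species, computes the wavelet modulus ratio map on the raw monthly
#' series and its pointwise IAAFT significance masks.
#'
#' @param config an [analysis_config()].
#' @return named list of [wmr_significance()] results, one per subset. When
#'   `out_dir` is set, writes `rho_<subset>.tsv` and `masks_<subset>.tsv`
#'   (scales in rows, months in columns; masks coded -1 low / 0 none / 1
#'   high / NA outside the cone) plus `run_meta.json`.
#' @export
run_wavelet_track <- function(config) {
  inp <- resolve_input(config)
  m <- inp$matrix
  scheme <- inp$scheme
  subsets <- list(community = colnames(m))
  if (!is.null(scheme)) {
    present <- intersect(colnames(m), names(scheme))
    for (g in sort(unique(unname(scheme[present]))))
      subsets[[g]] <- present[scheme[present] == g]
  }
  out <- list()
  for (sname in names(subsets)) {
    units <- subsets[[sname]]
    if (length(units) < 2L) {
      warning("subset ", sname, " has fewer than 2 units; skipped")
      next
    }
    out[[sname]] <- wmr_significance(
      m[, units, drop = FALSE], scales = config$scales,
      n_surrogates = config$n_surrogates, alpha = config$alpha,
      seed = config$seed + match(sname, names(subsets)) * 100000L,
      omega0 = config$omega0)
  }
  if (!is.null(config$out_dir)) write_wavelet_outputs(out, m, config)
  out
}

write_wavelet_outputs <- function(results, m, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  months <- rownames(m)
  for (sname in names(results)) {
    r <- results[[sname]]
    rho <- t(r$map$rho)
    dimnames(rho) <- list(sprintf("%.4f", r$map$scales), months)
    utils::write.table(data.frame(scale = rownames(rho), rho, check.names = FALSE),
                       file.path(config$out_dir, paste0("rho_", sname, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    mask <- matrix(0L, nrow(r$map$rho), ncol(r$map$rho))
    mask[r$significance$low_mask] <- -1L
    mask[r$significance$high_mask] <- 1L
    mask[is.na(r$map$rho)] <- NA_integer_
    mask <- t(mask)
    dimnames(mask) <- dimnames(rho)
    utils::write.table(data.frame(scale = rownames(mask), mask, check.names = FALSE),
                       file.path(config$out_dir, paste0("masks_", sname, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  meta <- list(track = "wavelet", omega0 = config$omega0, alpha = config$alpha,
               n_surrogates = config$n_surrogates, seed = config$seed,
               scales = results[[1]]$map$scales)
  jsonlite::write_json(meta, file.path(config$out_dir, "run_meta.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(results)
}

#' Simulate a community and write it in the long count format
#'
#' Closes the pipeline loop without any external data: the file written here
#' is read back by the analysis tracks.
#'
#' @param sim_config a [simulation_config()].
#' @param path output path for the tab-separated records.
#' @return the path, invisibly.
#' @export
run_simulate <- function(sim_config, path) {
  m <- simulate_forced_community(sim_config)
  write_count_records(as_count_records(m), path)
  invisible(path)
}
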