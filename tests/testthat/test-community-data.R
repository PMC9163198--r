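test_that("monthly matrix takes the per-cell maximum and zero-fills", {
  rec <- data.frame(year = c(1981, 1981, 1981), month = c(1, 1, 2),
                    species = "A", count = c(3, 7, 0))
  m <- build_monthly_matrix(rec, c("A", "B"),
                            list(start = c(1981, 1), end = c(1981, 2)))
  expect_equal(unclass(m), matrix(c(7, 0, 0, 0), 2, 2,
               dimnames = list(c("1981-01", "1981-02"), c("A", "B"))))

  empty <- data.frame(year = integer(0), month = integer(0),
                      species = character(0), count = numeric(0))
  m0 <- build_monthly_matrix(empty, "A", list(start = c(1990, 3), end = c(1990, 5)))
  expect_true(all(m0 == 0))
  expect_equal(dim(m0), c(3L, 1L))
})

test_that("monthly matrix equals a brute-force per-cell max over records", {
  species <- paste0("sp", 1:5)
  rec <- random_records(400, 1990:1991, species, seed = 11)
  m <- build_monthly_matrix(rec, species, list(start = c(1990, 1), end = c(1991, 12)))
  tm <- time_index(m)
  for (t in seq_len(nrow(m))) {
    for (i in seq_along(species)) {
      hits <- rec$count[rec$year == tm$year[t] & rec$month == tm$month[t] &
                        rec$species == species[i]]
      expect_equal(unname(m[t, i]), if (length(hits)) max(hits) else 0)
    }
  }
})

test_that("invalid records are rejected", {
  bad <- data.frame(year = 1990, month = 13, species = "A", count = 1)
  expect_error(build_monthly_matrix(bad, "A", list(start = c(1990, 1), end = c(1990, 12))),
               "month")
  neg <- data.frame(year = 1990, month = 2, species = "A", count = -1)
  expect_error(build_monthly_matrix(neg, "A", list(start = c(1990, 1), end = c(1990, 12))),
               "negative")
})

test_that("select_frequent ranks by occupancy, then abundance, then label", {
  vals <- cbind(a = c(1, 1, 1, 0), b = c(5, 9, 0, 0), c = c(0, 0, 0, 0))
  m <- abundance_matrix(vals, start = c(2000, 1))
  expect_equal(colnames(select_frequent(m, 2)), c("a", "b"))

  tied <- abundance_matrix(cbind(a = c(1, 2), b = c(5, 9), c = c(2, 2)),
                           start = c(2000, 1))
  expect_equal(colnames(select_frequent(tied, 1)), "b")
  expect_error(select_frequent(m, 4), "exceeds")
})

test_that("select_frequent matches an independent sort oracle", {
  set.seed(21)
  vals <- matrix(rpois(24 * 20, 1), 24, 20,
                 dimnames = list(NULL, sprintf("s%02d", 1:20)))
  m <- abundance_matrix(vals, start = c(2000, 1))
  occ <- apply(vals > 0, 2, sum)
  tot <- apply(vals, 2, sum)
  oracle <- colnames(vals)[order(-occ, -tot, colnames(vals))][1:10]
  expect_setequal(colnames(select_frequent(m, 10)), oracle)
})

test_that("group_sum sums members, drops unmapped species, conserves totals", {
  m <- abundance_matrix(cbind(A = c(1, 4), B = c(2, 5), C = c(7, 7)),
                        start = c(2000, 1))
  g <- group_sum(m, c(A = "G", B = "G"))
  expect_equal(unname(unclass(g)[, "G"]), c(3, 9))
  expect_equal(colnames(g), "G")

  single <- group_sum(m, c(A = "gA", B = "gB"))
  expect_equal(unname(unclass(single)), unname(unclass(m[, c("A", "B")])))

  set.seed(5)
  vals <- matrix(runif(36 * 6), 36, 6, dimnames = list(NULL, letters[1:6]))
  mm <- abundance_matrix(vals, start = c(1990, 1))
  scheme <- setNames(rep(c("g1", "g2"), each = 3), letters[1:6])
  gg <- group_sum(mm, scheme)
  for (t in 1:36) {
    expect_equal(unname(gg[t, "g1"]), sum(vals[t, 1:3]))
    expect_equal(unname(gg[t, "g2"]), sum(vals[t, 4:6]))
  }
  # one all-species group conserves the community total
  all_g <- group_sum(mm, setNames(rep("all", 6), letters[1:6]))
  expect_equal(unname(unclass(all_g)[, 1]), unname(rowSums(vals)))
  expect_error(group_sum(m, c(Z = "G")), "no unit")
})

test_that("seasonal means follow the warm and cold calendar rules", {
  vals <- matrix(0, 24, 1, dimnames = list(NULL, "A"))
  m <- abundance_matrix(vals, start = c(1990, 1))
  m[c("1990-05", "1990-06", "1990-07", "1990-08"), "A"] <- c(1, 2, 3, 6)
  warm <- seasonal_mean(m, "warm")
  expect_equal(unname(warm["1990", "A"]), 3.0)

  m[c("1990-11", "1990-12", "1991-01", "1991-02"), "A"] <- c(4, 4, 0, 0)
  cold <- seasonal_mean(m, "cold")
  expect_equal(unname(cold["1990", "A"]), 2.0)
  # 1991 cold season needs Nov 1991 .. Feb 1992, absent: edge season dropped
  expect_false("1991" %in% rownames(cold))
})

test_that("seasonal means agree with a calendar-slicing oracle over 35 years", {
  set.seed(9)
  n <- 35 * 12
  vals <- matrix(rpois(n * 3, 8), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  m <- abundance_matrix(vals, start = c(1981, 1))
  tm <- time_index(m)
  for (season in c("warm", "cold")) {
    got <- seasonal_mean(m, season)
    for (y in season_years_oracle(tm$year, season)) {
      rows <- if (season == "warm")
        which(tm$year == y & tm$month %in% 5:8)
      else
        c(which(tm$year == y & tm$month %in% 11:12),
          which(tm$year == y + 1 & tm$month %in% 1:2))
      if (length(rows) == 4)
        expect_equal(unname(got[as.character(y), ]), unname(colMeans(vals[rows, ])))
    }
  }
})

test_that("seasonal mean of a time-constant matrix is that constant", {
  vals <- matrix(rep(c(3, 7), each = 48), 48, 2, dimnames = list(NULL, c("a", "b")))
  m <- abundance_matrix(vals, start = c(2000, 1))
  for (season in c("warm", "cold")) {
    s <- seasonal_mean(m, season)
    expect_true(all(s[, "a"] == 3) && all(s[, "b"] == 7))
  }
})

test_that("grouping and seasonal averaging commute (linearity)", {
  set.seed(31)
  vals <- matrix(runif(120 * 4, 0, 20), 120, 4, dimnames = list(NULL, letters[1:4]))
  m <- abundance_matrix(vals, start = c(1995, 1))
  scheme <- setNames(c("g1", "g1", "g2", "g2"), letters[1:4])
  a <- seasonal_mean(group_sum(m, scheme), "warm")
  b <- seasonal_mean(m, "warm")
  expect_equal(unname(a[, "g1"]), unname(b[, "a"] + b[, "b"]))
  expect_equal(unname(a[, "g2"]), unname(b[, "c"] + b[, "d"]))
})

test_that("period split is half-open at the cut year", {
  s <- seasonal_series(matrix(1:10, 5, 2), 2004:2008, "warm")
  sp <- split_period(s, 2006)
  expect_equal(season_years_of(sp$pre), 2004:2005)
  expect_equal(season_years_of(sp$post), 2006:2008)
  expect_warning(split_period(s, 2000), "one side")
  expect_warning(split_period(s, 2050), "one side")
  expect_equal(nrow(suppressWarnings(split_period(s, 2000))$pre), 0L)
  expect_equal(nrow(suppressWarnings(split_period(s, 2050))$post), 0L)
})

test_that("biomass conversion multiplies cells by species mass", {
  m <- abundance_matrix(cbind(A = c(10, 0), B = c(2, 3)), start = c(2000, 1))
  b <- to_biomass(m, c(A = 60, B = 1000))
  expect_equal(unname(b[1, "A"]), 600)
  expect_equal(unname(unclass(to_biomass(m, c(A = 1, B = 1)))), unname(unclass(m)))
  set.seed(13)
  vals <- matrix(rpois(40, 4), 20, 2, dimnames = list(NULL, c("A", "B")))
  mm <- abundance_matrix(vals, start = c(2000, 1))
  masses <- c(A = runif(1, 10, 100), B = runif(1, 10, 100))
  bb <- to_biomass(mm, masses)
  for (j in 1:2) expect_equal(unname(unclass(bb)[, j]), vals[, j] * masses[j])
  expect_error(to_biomass(m, c(A = 60)), "B")
})

test_that("count records and matrices round-trip through delimited text", {
  m <- make_synchronous(48, 3, seed = 4)
  rec_path <- withr::local_tempfile(fileext = ".tsv")
  write_count_records(as_count_records(m), rec_path)
  rec <- read_count_records(rec_path)
  m2 <- build_monthly_matrix(rec, colnames(m),
                             list(start = c(2000, 1), end = c(2003, 12)))
  expect_equal(unclass(m2), unclass(m))
  mat_path <- withr::local_tempfile(fileext = ".tsv")
  write_abundance_matrix(m, mat_path)
  tab <- read.delim(mat_path, check.names = FALSE)
  expect_equal(tab$time, rownames(m))
  expect_equal(as.matrix(tab[, -1]), unclass(m), ignore_attr = TRUE)
})
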