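test_that("Morlet response to a sinusoid peaks at the analytic scale", {
  x <- 100 + 50 * sin(2 * pi * (1:240) / 12)
  wf <- morlet_cwt(x)
  peak <- wf$scales[which.max(Mod(wf$coef[120, ]))]
  voice_step <- 2^(1 / 12)
  expect_lt(abs(log(peak / period_to_scale(12))), log(voice_step))
})

test_that("the transform is zero for constants and linear in amplitude", {
  wf0 <- morlet_cwt(rep(5, 64))
  expect_true(all(Mod(wf0$coef) < 1e-12))
  x <- seasonal_series_fixture(64)
  w1 <- morlet_cwt(x)
  w3 <- morlet_cwt(3 * x)
  expect_equal(Mod(w3$coef), 3 * Mod(w1$coef), tolerance = 1e-10)
  expect_error(morlet_cwt(x, scales = c(1, 4)), "scales")
  expect_error(morlet_cwt(x, scales = c(4, 40)), "scales")
})

test_that("rho is 1 for identical series at every unmasked cell", {
  x <- seasonal_series_fixture(240)
  m <- matrix(rep(x, 4), 240, 4)
  map <- wavelet_modulus_ratio(m)
  ok <- !is.na(map$rho)
  expect_gt(sum(ok), 0)
  expect_lt(max(abs(map$rho[ok] - 1)), 1e-10)
})

test_that("rho vanishes at the oscillation scale for equal antiphase units", {
  m <- make_antiphase_pair(240, period = 12, a1 = 50, a2 = 50)
  map <- wavelet_modulus_ratio(m)
  j <- which.min(abs(map$scales - period_to_scale(12)))
  mid <- which(map$times >= 100 & map$times <= 140)
  expect_lt(min(map$rho[mid, j]), 0.05)
})

test_that("a single unit has rho identically 1", {
  x <- seasonal_series_fixture(128)
  map <- wavelet_modulus_ratio(matrix(x, ncol = 1))
  ok <- !is.na(map$rho)
  expect_lt(max(abs(map$rho[ok] - 1)), 1e-10)
})

test_that("rho stays in [0, 1] on random communities", {
  for (k in 1:5) {
    m <- unclass(make_independent(96, 4, ar_coefficient = 0.4, seed = 700 + k))
    map <- wavelet_modulus_ratio(m)
    ok <- !is.na(map$rho)
    expect_true(all(map$rho[ok] >= -1e-12 & map$rho[ok] <= 1 + 1e-12))
  }
})

test_that("rho matches an explicit-loop evaluation of the smoothed ratio", {
  set.seed(77)
  m <- cbind(seasonal_series_fixture(128, seed = 1),
             seasonal_series_fixture(128, seed = 2),
             5 + cumsum(rnorm(128, sd = 0.3)))
  m[m < 0] <- 0
  fields <- lapply(1:3, function(j) morlet_cwt(m[, j]))
  map <- wavelet_modulus_ratio(fields)
  oracle <- wmr_loop_oracle(fields)
  expect_equal(map$rho, oracle, tolerance = 1e-10)
})

test_that("rho is invariant to common rescaling but not to single-unit dominance", {
  m <- unclass(make_antiphase_pair(192, 12, 40, 40, noise_sd = 1, seed = 6))
  map1 <- wavelet_modulus_ratio(m)
  map2 <- wavelet_modulus_ratio(m * 4.2)
  expect_equal(map1$rho, map2$rho, tolerance = 1e-10)

  # dominance: as one antiphase unit outweighs the other, compensation at the
  # oscillation scale becomes unreachable and rho rises toward 1
  min_rho <- vapply(c(1, 3, 10, 50), function(a_ratio) {
    mm <- make_antiphase_pair(192, 12, a1 = 40 * a_ratio, a2 = 40)
    map <- wavelet_modulus_ratio(mm)
    j <- which.min(abs(map$scales - period_to_scale(12)))
    mid <- which(map$times >= 80 & map$times <= 112)
    min(map$rho[mid, j])
  }, numeric(1))
  expect_true(all(diff(min_rho) > 0))
  expect_gt(min_rho[4], 0.9)
})

test_that("rho of antiphase guild sums is reduced relative to a synchronized community", {
  sim_rho <- function(opposed) {
    m <- simulate_forced_community(
      simulation_config(n_species_per_guild = 4, n_months = 240,
                        sign_opposed = opposed, seed = 15))
    scheme <- setNames(sub("_.*", "", colnames(m)), colnames(m))
    sums <- group_sum(m, scheme)
    map <- wavelet_modulus_ratio(unclass(sums))
    j <- which.min(abs(map$scales - period_to_scale(12)))
    mean(map$rho[!is.na(map$rho[, j]), j])
  }
  expect_gt(sim_rho(FALSE), sim_rho(TRUE))
  expect_gt(sim_rho(FALSE), 0.8)
})

test_that("significance masks flag synchrony, obey the p floor and the level", {
  x <- seasonal_series_fixture(96, seed = 3)
  m <- cbind(x, x, x)
  res <- wmr_significance(m, n_surrogates = 60, alpha = 0.10, seed = 42)
  ok <- !is.na(res$map$rho)
  # surrogates destroy cross-unit phase locking: identical series sit in the
  # extreme upper tail over most of the plane
  expect_gt(mean(res$significance$high_mask[ok]), 0.5)
  expect_false(any(res$significance$low_mask & res$significance$high_mask))

  # a single surrogate can never beat alpha / 2
  res1 <- wmr_significance(m, n_surrogates = 1, alpha = 0.10, seed = 1)
  expect_false(any(res1$significance$low_mask))
  expect_false(any(res1$significance$high_mask))

  # degenerate level: essentially every unmasked cell lands on one side
  resa <- wmr_significance(m, n_surrogates = 15, alpha = 1.0, seed = 9)
  flagged <- resa$significance$low_mask | resa$significance$high_mask
  expect_gt(mean(flagged[ok]), 0.99)
})

test_that("surrogate rho is stochastically below observed rho for synchronized series", {
  m <- unclass(make_synchronous(96, 4, noise_sd = 0.3, seed = 21))
  obs <- wavelet_modulus_ratio(m)
  j <- which.min(abs(obs$scales - period_to_scale(12)))
  ok <- !is.na(obs$rho[, j])
  surr_mean <- vapply(1:50, function(k) {
    set.seed(k)
    s <- apply(m, 2, iaaft_surrogate)
    mean(wavelet_modulus_ratio(s, scales = obs$scales)$rho[ok, j])
  }, numeric(1))
  expect_gt(mean(obs$rho[ok, j]), mean(surr_mean))
})
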