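test_that("radiant exposure reproduces the assay doses", {
  expect_equal(round(radiant_exposure(1.24, 7.5), 1), 9.3)
  expect_equal(round(radiant_exposure(1.34, 15.0), 1), 20.1)
  expect_equal(radiant_exposure(1.24, 0), 0)
  expect_error(radiant_exposure(-1, 5), "non-negative")
})

mk_kin <- function(k, extract = "s", light = "blue", noise = 0, seed = NULL,
                   condition = "DMA", reps = 1L) {
  t <- seq(0, 20, by = 5)
  if (!is.null(seed)) set.seed(seed)
  do.call(rbind, lapply(seq_len(reps), function(r)
    dma_kinetics(extract, light, condition, t,
                 1 - k * t + rnorm(length(t), 0, noise), replicate = r)))
}

test_that("DMA relative yield: identity, zero decay, planted ratio", {
  ctl <- mk_kin(0.008)
  expect_equal(dma_relative_yield(ctl, ctl)$yield, 100)
  flat <- mk_kin(0)
  expect_equal(dma_relative_yield(flat, ctl)$yield, 0)
  half <- mk_kin(0.004)
  expect_equal(dma_relative_yield(half, ctl)$yield, 50, tolerance = 1e-9)
  expect_error(dma_relative_yield(ctl, flat), "inactive positive control")
  grn <- mk_kin(0.004, light = "green")
  expect_error(dma_relative_yield(grn, ctl), "light source")
})

test_that("DMA yield is invariant to a common absorbance scale", {
  s <- mk_kin(0.004, noise = 0.002, seed = 41)
  c0 <- mk_kin(0.008, noise = 0.002, seed = 42)
  y1 <- dma_relative_yield(s, c0)$yield
  s2 <- s; s2$a377 <- s2$a377 * 7
  c2 <- c0; c2$a377 <- c2$a377 * 7
  expect_equal(dma_relative_yield(s2, c2)$yield, y1, tolerance = 1e-9)
})

test_that("ascorbate protection diagnostic", {
  dma <- mk_kin(0.01)
  expect_equal(type1_protection(dma, dma), 0)
  none <- mk_kin(0)
  expect_equal(type1_protection(dma, none), 1)
  quenched <- mk_kin(0.007)
  expect_equal(type1_protection(dma, quenched), 0.3, tolerance = 1e-9)
  expect_true(is.na(type1_protection(none, none)))
})

test_that("Hill fit recovers noise-free parameters and censors flat curves", {
  v <- hill_viability(dose_ladder, ec50 = 10, h = 1)
  f <- fit_hill(dose_ladder, v)
  expect_equal(f$ec50, 10, tolerance = 1e-6)
  expect_equal(f$hill_slope, 1, tolerance = 1e-4)
  expect_false(f$censored)
  expect_true(f$ci95[1] <= f$ec50 && f$ec50 <= f$ci95[2])
  expect_equal(predict(f, 10), 50, tolerance = 1e-4)
  expect_equal(unname(coef(f)["ec50"]), 10, tolerance = 1e-6)

  set.seed(51)
  flat <- fit_hill(rep(dose_ladder, 3), rep(92, 18) + rnorm(18, 0, 3),
                   c_max = 37.5)
  expect_true(flat$censored)
  expect_equal(flat$ec50, 37.5)

  expect_error(fit_hill(c(1, 2, 3), c(90, 50, 10)), "4 distinct")
})

test_that("Hill fit has steep-slope and replicate support", {
  v <- hill_viability(dose_ladder, ec50 = 4, h = 3)
  f <- fit_hill(dose_ladder, v)
  expect_equal(f$ec50, 4, tolerance = 1e-5)
  expect_equal(f$hill_slope, 3, tolerance = 1e-3)
  set.seed(52)
  d3 <- rep(dose_ladder, 3)
  f3 <- fit_hill(d3, hill_viability(d3, 5) + rnorm(18, 0, 5))
  expect_false(f3$censored)
  expect_gt(f3$ec50, 1); expect_lt(f3$ec50, 25)
  expect_length(residuals(f3), 18L)
})

test_that("selectivity index reproduces the worked examples and invariants", {
  dark <- censored_ec50(37.5)
  si_ags <- selectivity_index(dark, list(ec50 = 0.8))
  expect_equal(round(si_ags$value, 1), 46.9)
  expect_true(si_ags$lower_bound)
  expect_equal(round(selectivity_index(dark, list(ec50 = 1.6))$value, 1), 23.4)
  expect_equal(round(selectivity_index(dark, list(ec50 = 2.1))$value, 1), 17.9)

  x <- list(ec50 = 12, censored = FALSE)
  expect_equal(selectivity_index(x, x)$value, 1)
  expect_false(selectivity_index(x, x)$lower_bound)
  si_seq <- sapply(c(0.5, 1, 2, 4), function(e)
    selectivity_index(dark, list(ec50 = e))$value)
  expect_true(all(diff(si_seq) < 0))
  expect_error(selectivity_index(dark, list(ec50 = 0)), "positive")
})

test_that("photocytotoxicity bands match the published classification", {
  expect_identical(classify_photocytotoxicity(3.7), "very high")
  expect_identical(classify_photocytotoxicity(11.1), "high")
  expect_identical(classify_photocytotoxicity(25.0), "no/low")
  expect_identical(classify_photocytotoxicity(c(5, 20)), c("high", "high"))
  expect_error(classify_photocytotoxicity(0), "positive")
})
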