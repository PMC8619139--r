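mk_table <- function(areas, extracts = paste0("ex", seq_len(ncol(areas)))) {
  colnames(areas) <- extracts
  feature_table(data.frame(feature_id = paste0("F", seq_len(nrow(areas))),
                           mz = 300 + seq_len(nrow(areas)),
                           rt = seq_len(nrow(areas)),
                           stringsAsFactors = FALSE), areas)
}

test_that("specificity shares are area fractions; degenerate features flagged", {
  tbl <- mk_table(rbind(c(3, 1, 0), c(0, 5, 0), c(0, 0, 0)))
  sp <- feature_specificity(tbl)
  expect_equal(unlist(sp[1, c("ex1", "ex2", "ex3")], use.names = FALSE),
               c(0.75, 0.25, 0))
  expect_equal(sp$max_share[2], 1.0)
  expect_identical(sp$max_extract[2], "ex2")
  expect_true(sp$degenerate[3])
  expect_equal(unlist(sp[3, c("ex1", "ex2", "ex3")], use.names = FALSE),
               c(0, 0, 0))
})

test_that("non-degenerate shares sum to one across random tables", {
  set.seed(21)
  for (i in 1:20) {
    areas <- matrix(rexp(24), 4, 6)
    areas[sample(24, 5)] <- 0
    sp <- feature_specificity(mk_table(areas))
    sums <- rowSums(sp[, paste0("ex", 1:6)])
    expect_equal(sums[!sp$degenerate], rep(1, sum(!sp$degenerate)),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("specificity counts use strict inequality and are monotone in level", {
  tbl <- mk_table(rbind(c(97, 3, 0), c(100, 0, 0), c(40, 35, 25)))
  sp <- feature_specificity(tbl)
  expect_equal(count_specific_features(sp, 0.99)[["ex1"]], 1L)  # 0.97 excluded
  expect_equal(count_specific_features(sp, 0.95)[["ex1"]], 2L)  # 0.97 counted
  expect_error(count_specific_features(sp, 1.2), "level")
  levels <- c(0.60, 0.95, 0.99)
  counts <- sapply(levels, function(l) sum(count_specific_features(sp, l)))
  expect_true(all(diff(counts) <= 0))
  # restriction to a VIS-positive subset
  expect_equal(count_specific_features(sp, 0.95, restrict_to = "F2")[["ex1"]], 1L)
})

test_that("VIS signal: flat trace is negative, planted peak is positive", {
  grid <- seq(0, 10, by = 0.01)
  flat <- dad_trace("e", 468, grid, rep(0, length(grid)))
  r <- extract_vis_signal(5, list(flat))
  expect_equal(r$flag, 0L)
  expect_equal(r$snr, 0)

  set.seed(31)
  noise <- rnorm(length(grid), 0, 0.5)
  peak50 <- dad_trace("e", 468, grid, noise + 25 * exp(-(grid - 5)^2 / (2 * 0.05^2)))
  expect_equal(extract_vis_signal(5, list(peak50))$flag, 1L)
  # same shape scaled to the noise floor stays negative
  peak1 <- dad_trace("e", 468, grid, noise + 0.5 * exp(-(grid - 5)^2 / (2 * 0.05^2)))
  expect_equal(extract_vis_signal(5, list(peak1))$flag, 0L)
})

test_that("VIS snr is amplitude-monotone and scale-invariant", {
  grid <- seq(0, 10, by = 0.01)
  set.seed(32)
  noise <- rnorm(length(grid), 0, 0.5)
  snrs <- sapply(c(0.5, 2, 8, 25), function(amp) {
    tr <- dad_trace("e", 468, grid, noise + amp * exp(-(grid - 5)^2 / (2 * 0.05^2)))
    extract_vis_signal(5, list(tr))$snr
  })
  expect_true(all(diff(snrs) > 0))
  tr1 <- dad_trace("e", 468, grid, noise + 8 * exp(-(grid - 5)^2 / (2 * 0.05^2)))
  tr2 <- dad_trace("e", 468, grid, 2 * (noise + 8 * exp(-(grid - 5)^2 / (2 * 0.05^2))))
  expect_equal(extract_vis_signal(5, list(tr1))$snr,
               extract_vis_signal(5, list(tr2))$snr, tolerance = 1e-9)
})

test_that("assign_vis_flags recovers the planted chromophores exactly", {
  ds <- generate_dataset(small_config(seed = 9))
  vis <- assign_vis_flags(ds$table, ds$traces)
  truth <- ds$info$chromophore[match(vis$feature_id, ds$info$feature_id)]
  expect_identical(vis$flag == 1L, truth)  # precision and recall 1
  # no traces at all: every flag 0
  vis0 <- assign_vis_flags(ds$table, list())
  expect_true(all(vis0$flag == 0L))
  # wrong-wavelength traces are skipped with a warning (one per trace)
  w <- capture_warnings(v519 <- assign_vis_flags(ds$table, ds$traces,
                                                 wavelength = 519))
  expect_length(w, length(ds$traces))
  expect_true(all(grepl("skipping", w)))
  expect_true(all(v519$flag == 0L))
})
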