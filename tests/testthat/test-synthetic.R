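test_that("generator is deterministic per seed and sensitive to it", {
  a <- generate_dataset(small_config(seed = 5))
  b <- generate_dataset(small_config(seed = 5))
  expect_identical(a$spectra, b$spectra)
  expect_identical(a$table$areas, b$table$areas)
  expect_identical(a$dma, b$dma)
  expect_identical(a$dose_response, b$dose_response)
  c0 <- generate_dataset(small_config(seed = 6))
  expect_false(identical(a$spectra, c0$spectra))
})

test_that("bundles are byte-identical for identical seed and config", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_bundle(small_config(seed = 5), d1, force = TRUE)
  generate_bundle(small_config(seed = 5), d2, force = TRUE)
  files <- list.files(d1)
  expect_setequal(files, list.files(d2))
  for (f in files)
    expect_identical(readBin(file.path(d1, f), "raw", 2e6),
                     readBin(file.path(d2, f), "raw", 2e6),
                     label = f)
  manifest <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_setequal(unlist(manifest$files), files)
  expect_error(generate_bundle(small_config(seed = 5), d1), "not empty")
})

test_that("spectrum families have the planted similarity structure", {
  plan1 <- data.frame(family = "A", size = 1L, extract = "callisteus",
                      chromophore = FALSE, specific = FALSE)
  one <- generate_spectra(generator_config(seed = 2, family_plan = plan1))
  expect_length(one$spectra, 1L)

  ds <- generate_dataset(generator_config(seed = 14))
  fam <- ds$families
  ids <- names(fam)
  set.seed(14)
  pick <- sample(length(ids), 40)
  within <- c(); between <- c()
  for (i in pick) {
    j <- sample(setdiff(seq_along(ids), i), 1)
    s <- modified_cosine(ds$spectra[[i]], ds$spectra[[j]])$score
    if (fam[i] == fam[j]) within <- c(within, s) else between <- c(between, s)
  }
  # score separation: within-family pairs beat between-family pairs
  expect_true(all(between < 0.5))
  ex <- which(fam == fam[[1]])
  ws <- sapply(ex[-1], function(j)
    modified_cosine(ds$spectra[[ex[1]]], ds$spectra[[j]])$score)
  expect_true(all(ws >= 0.7))
})

test_that("ground truth is self-consistent with the emitted tables", {
  ds <- generate_dataset(generator_config(seed = 15))
  sp <- feature_specificity(ds$table)
  planned <- ds$info[ds$info$specific, ]
  m <- match(planned$feature_id, sp$feature_id)
  expect_true(all(sp$max_extract[m] == planned$extract))
  expect_true(all(sp$max_share[m] > 0.99))
  # planted non-specific features stay below the complete-specificity level
  unplanned <- ds$info[!ds$info$specific, ]
  expect_true(all(sp$max_share[match(unplanned$feature_id, sp$feature_id)] < 0.99))
})

test_that("generated assays embed the designed truth", {
  cfg <- small_config(seed = 16)
  assays <- generate_assays(cfg)
  # zero-noise config: Hill fit recovers the true EC50 almost exactly
  cfg0 <- small_config(seed = 16)
  cfg0$viability_sd <- 0
  dr0 <- generate_assays(cfg0)$dose_response
  row <- cfg0$true_ec50[cfg0$true_ec50$light == "green" &
                          cfg0$true_ec50$extract_id == "xanthophyllus" &
                          cfg0$true_ec50$cell_line == "AGS", ]
  sub <- dr0[dr0$extract_id == "xanthophyllus" & dr0$cell_line == "AGS" &
               dr0$light == "green", ]
  f <- fit_hill(sub$concentration, sub$viability, c_max = 37.5)
  expect_equal(f$ec50, row$ec50, tolerance = 1e-6)
  # dark series are censored by design
  subd <- dr0[dr0$extract_id == "xanthophyllus" & dr0$cell_line == "AGS" &
                dr0$light == "dark", ]
  fd <- fit_hill(subd$concentration, subd$viability, c_max = 37.5)
  expect_true(fd$censored)
  # DMA series with zero photoactivity are flat
  cfg_flat <- small_config(seed = 17)
  cfg_flat$true_yields$blue <- 0
  cfg_flat$dma_noise_sd <- 0
  dma <- generate_assays(cfg_flat)$dma
  flat <- dma[dma$extract_id == "callisteus" & dma$light == "blue" &
                dma$condition == "DMA", ]
  expect_equal(diff(range(flat$a377)), 0)
})
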