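spec2 <- function(id, prec, mz, inten) {
  fragment_spectrum(id, prec, peaks = cbind(mz, inten))
}

test_that("match_peaks finds direct and precursor-shifted candidates", {
  a <- spec2("a", 300, c(100, 200), c(1, 1))
  b <- spec2("b", 300, c(100, 200), c(1, 1))
  direct <- match_peaks(a, b, 0.02)
  expect_equal(nrow(direct[direct$index_a == direct$index_b, ]), 2L)

  a2 <- spec2("a", 300, 150, 1)
  b2 <- spec2("b", 314, 164, 1)  # 164 - (314 - 300) = 150: shifted match
  shifted <- match_peaks(a2, b2, 0.02)
  expect_equal(nrow(shifted), 1L)
  expect_true(shifted$shifted)

  disj <- match_peaks(spec2("a", 300, 100, 1), spec2("b", 300, 250, 1), 0.02)
  expect_equal(nrow(disj), 0L)

  expect_error(match_peaks(a, b, 0), "frag_tol")
})

test_that("modified cosine: identity, analog worked example, empty cases", {
  a <- spec2("a", 300, c(100, 150, 210), c(5, 1, 3))
  self <- modified_cosine(a, a)
  expect_equal(self$score, 1, tolerance = 1e-9)
  expect_equal(self$n_matched, 3L)

  # one direct + one shifted match with perfectly correlated intensities
  x <- spec2("x", 300, c(100, 150), c(1, 0.25))
  y <- spec2("y", 314, c(100, 164), c(1, 0.25))
  mc <- modified_cosine(x, y, 0.02)
  expect_equal(mc$score, 1, tolerance = 1e-9)
  expect_equal(mc$n_matched, 2L)

  none <- modified_cosine(spec2("a", 300, 100, 1), spec2("b", 300, 250, 1))
  expect_equal(none$score, 0)
  expect_equal(none$n_matched, 0L)

  e1 <- fragment_spectrum("e1", 300)
  e2 <- fragment_spectrum("e2", 310)
  both <- modified_cosine(e1, e2)
  expect_equal(both$score, 0)
})

test_that("modified cosine is symmetric and bounded on random pairs", {
  set.seed(71)
  for (i in 1:50) {
    pr <- random_spectrum_pair(6L)
    ab <- modified_cosine(pr$a, pr$b)
    ba <- modified_cosine(pr$b, pr$a)
    expect_equal(ab$score, ba$score, tolerance = 1e-9)
    expect_gte(ab$score, 0)
    expect_lte(ab$score, 1)
  }
})

test_that("greedy assignment matches the exhaustive oracle on small spectra", {
  set.seed(72)
  for (i in 1:60) {
    pr <- random_spectrum_pair(6L)
    expect_equal(modified_cosine(pr$a, pr$b)$score,
                 oracle_modified_cosine(pr$a, pr$b),
                 tolerance = 1e-9)
  }
})

test_that("build_network applies threshold, mutual top-k and size cap", {
  # single spectrum: one singleton, no edges
  one <- build_network(list(spec2("s", 300, c(100, 110), c(1, 1))))
  expect_equal(nrow(one$edges), 0L)
  expect_identical(one$singletons, "s")

  expect_error(build_network(list(spec2("s", 300, 100, 1),
                                  spec2("s", 310, 100, 1))), "duplicate")

  # triangle with ranked scores: with top_k = 1 only the best edge survives,
  # because B-C is rank 2 for B and A-C is rank 2 for A
  base <- c(100, 120, 140, 160, 180, 200)
  A <- spec2("A", 300, base, c(10, 9, 8, 7, 6, 5))
  B <- spec2("B", 300, base, c(10, 9, 8, 7, 6, 4))
  C <- spec2("C", 300, base, c(10, 9, 8, 7, 6, 0.5))
  sAB <- modified_cosine(A, B)$score
  sBC <- modified_cosine(B, C)$score
  sAC <- modified_cosine(A, C)$score
  expect_true(sAB > sBC && sBC > sAC && sAC > 0.7)
  net <- build_network(list(A, B, C), top_k = 1L)
  expect_equal(nrow(net$edges), 1L)
  expect_setequal(c(net$edges$feature_a, net$edges$feature_b), c("A", "B"))
  expect_identical(net$singletons, "C")

  # max_component_size splits by removing lowest-scoring edges
  netcap <- build_network(list(A, B, C), max_component_size = 2L)
  sizes <- table(netcap$components)
  expect_true(all(sizes <= 2L))
})

test_that("networking recovers planted analog families", {
  ds <- generate_dataset(small_config(seed = 8))
  net <- build_network(ds$spectra)
  # each family forms exactly one component
  fam_of <- ds$families[names(net$components)]
  expect_equal(length(unique(net$components)), length(unique(fam_of)))
  tab <- table(fam_of, net$components)
  expect_true(all(rowSums(tab > 0) == 1L))
  # post-conditions
  expect_true(all(net$edges$score >= 0.7))
  expect_true(all(net$edges$n_matched >= 6L))
  expect_true(all(table(net$components) <= 100L))
})
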