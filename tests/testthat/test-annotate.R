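mk_entry <- function(name, prec, mz, inten, taxonomy = character(0),
                     marker = FALSE) {
  library_entry(name, fragment_spectrum(paste0("lib_", name), prec,
                                        peaks = cbind(mz, inten)),
                taxonomy = taxonomy, marker = marker)
}

scaffold <- c(120.5, 151.2, 190.7, 220.3, 251.9, 280.4, 310.8, 340.2)
inten <- c(10, 40, 100, 25, 60, 15, 80, 30)

test_that("library matching: identity hit, analog hit, empty library", {
  lib <- list(mk_entry("dermorubin", 400.1, scaffold, inten, marker = TRUE),
              mk_entry("other", 900.5, scaffold + 450, inten))
  query <- fragment_spectrum("F1", 400.1, peaks = cbind(scaffold, inten))
  hits <- library_match(query, lib)
  expect_equal(hits$name[1], "dermorubin")
  expect_equal(hits$base_score[1], 1, tolerance = 1e-9)
  expect_equal(hits$identification_level[1], 1L)  # marker + precursor match

  # methylated analog: shifted precursor and shifted substitution-site peaks
  mz_me <- scaffold; mz_me[c(2, 5)] <- mz_me[c(2, 5)] + 14.0157
  analog <- fragment_spectrum("F2", 400.1 + 14.0157,
                              peaks = cbind(sort(mz_me), inten[order(mz_me)]))
  hits2 <- library_match(analog, lib)
  expect_equal(hits2$name[1], "dermorubin")
  expect_gt(hits2$base_score[1], 0.7)
  expect_equal(hits2$identification_level[1], 2L)  # precursor differs: level 2

  expect_warning(h0 <- library_match(query, list()), "empty")
  expect_equal(nrow(h0), 0L)
})

test_that("taxonomic re-ranking boosts matching lineages, preserves hits", {
  lib <- list(
    mk_entry("fungal", 400.1, scaffold, inten,
             taxonomy = c(family = "Cortinariaceae", genus = "Cortinarius")),
    mk_entry("plantal", 400.1, scaffold, inten,
             taxonomy = c(family = "Asteraceae")),
    mk_entry("anon", 400.1, scaffold, inten))
  query <- fragment_spectrum("F1", 400.1, peaks = cbind(scaffold, inten))
  hits <- library_match(query, lib)
  expect_equal(length(unique(hits$base_score)), 1L)  # equal base scores
  sample_tax <- c(family = "Cortinariaceae", genus = "Cortinarius",
                  species = "xanthophyllus")

  same <- taxonomic_rerank(hits, sample_tax, weights = c(species = 0, genus = 0,
                                                         family = 0))
  expect_identical(same$name, hits$name)  # all-zero weights: order unchanged

  rr <- taxonomic_rerank(hits, sample_tax)
  expect_equal(rr$name[1], "fungal")
  expect_equal(rr$tax_boost[rr$name == "fungal"], 0.15)  # family + genus
  expect_equal(rr$tax_boost[rr$name == "anon"], 0)
  expect_setequal(rr$name, hits$name)  # permutation, nothing dropped
  expect_equal(rr$final_score, rr$base_score + rr$tax_boost)
  # boost is monotone in the number of matching ranks
  expect_true(rr$tax_boost[rr$name == "fungal"] >
                rr$tax_boost[rr$name == "plantal"])
  expect_error(taxonomic_rerank(hits, sample_tax, weights = c(family = -1)),
               "non-negative")
})

test_that("marker propagation tags whole clusters, and only those", {
  ds <- generate_dataset(small_config(seed = 13))
  net <- build_network(ds$spectra)
  fam_a <- names(ds$families)[ds$families == "A"]
  # marker library entry = first member of family A
  marker_spec <- ds$spectra[[match(fam_a[1], vapply(ds$spectra, `[[`, "",
                                                    "feature_id"))]]
  lib <- list(library_entry("dermolutein", marker_spec, marker = TRUE))
  hits <- do.call(rbind, lapply(ds$spectra, library_match, library = lib))
  expect_true(any(hits$identification_level == 1L))
  tagged <- propagate_markers(net, hits)
  got <- tagged$nodes$marker_family[match(fam_a, tagged$nodes$feature_id)]
  expect_true(all(got == "dermolutein"))  # every family-A analog tagged
  others <- tagged$nodes$marker_family[!tagged$nodes$feature_id %in% fam_a]
  expect_true(all(is.na(others)))

  # no level-1 hits: nothing propagates
  none <- propagate_markers(net, hits[hits$identification_level != 1L, ])
  expect_true(all(is.na(none$nodes$marker_family)))
})
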