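# Ground-truth synthetic data generator. Emulates the statistical structure
# the analysis assumes: compound families sharing fragment scaffolds with
# analog mass shifts, species-specific peak-area patterns (including
# >99%-specific features), chromophore DAD peaks at feature retention times,
# first-order DMA photobleaching, and Hill-shaped dose-response with
# light-dependent EC50 shifts. Every stage of the pipeline can be tested
# against the planted truth without any external download.

# Mass shifts of the derivatizations the annotation stage must recognize.
ANALOG_SHIFTS <- c(methylation = 14.0157, oxidation = 15.9949,
                   glycosylation = 162.0528, chlorination = 33.9610)

default_family_plan <- function() {
  data.frame(
    family = c(paste0("AQX", 1:7), paste0("AQR", 1:2), paste0("BG", 1:6)),
    size = c(12L, 8L, 8L, 7L, 7L, 6L, 4L, 5L, 4L, rep(5L, 6L)),
    extract = c(rep("xanthophyllus", 7L), rep("rubrophyllus", 2L),
                "callisteus", "traganus", "trivialis", "venetus",
                "callisteus", "traganus"),
    chromophore = c(rep(TRUE, 9L), rep(FALSE, 6L)),
    specific = c(rep(TRUE, 9L), rep(FALSE, 6L)),
    stringsAsFactors = FALSE)
}

default_true_yields <- function() {
  data.frame(
    extract_id = c("callisteus", "traganus", "trivialis", "venetus",
                   "rubrophyllus", "xanthophyllus"),
    blue = c(2.0, 3.0, 1.5, 2.5, 123.2, 183.5),
    green = c(1.5, 2.0, 1.0, 2.5, 11.3, 10.0),
    stringsAsFactors = FALSE)
}

default_true_ec50 <- function() {
  lines <- c("A549", "AGS", "T24", "NIH3T3")
  irr <- data.frame(extract_id = "xanthophyllus", cell_line = lines,
                    light = "green", ec50 = c(1.6, 0.8, 1.2, 2.1), hill = 1.5,
                    stringsAsFactors = FALSE)
  irr2 <- data.frame(extract_id = "rubrophyllus", cell_line = lines,
                     light = "green", ec50 = c(18, 15, 12, 19), hill = 1.2,
                     stringsAsFactors = FALSE)
  dark <- expand.grid(extract_id = c("xanthophyllus", "rubrophyllus"),
                      cell_line = lines, stringsAsFactors = FALSE)
  dark$light <- "dark"
  dark$ec50 <- 200   # beyond the top tested dose: censored by design
  dark$hill <- 1.0
  rbind(irr, irr2, dark[, names(irr)])
}

#' Generator configuration
#'
#' Fixes every parameter of the synthetic-data generator. The defaults define
#' the reference study conditions: six extracts (two photoactive, four
#' inactive), nine >99%-specific chromophore features planted in the
#' rubrophyllus-like extract and 52 in the xanthophyllus-like one, the
#' 6-point dose ladder 0.375-37.5 ug/mL in triplicate, and DMA kinetics with
#' a t = 0 read plus four irradiation cycles.
#'
#' @param seed Integer seed (mandatory); the bundle is a deterministic
#'   function of (seed, config).
#' @param family_plan data.frame(family, size, extract, chromophore,
#'   specific): compound families, their analog counts, majority extract,
#'   whether members carry a visible-light chromophore, and whether they are
#'   planted as >99%-specific.
#' @param extracts Extract names; defaults to the six species roles.
#' @param rt_spacing Minutes between feature retention-time slots (0.5, so
#'   adjacent peaks of sd 0.05 min are baseline-resolved in the DAD traces).
#' @param specific_share Share planted for specific features (0.995).
#' @param dad_noise_sd DAD baseline noise sd in mAU (0.5).
#' @param dad_amp_snr Chromophore DAD peak amplitude in units of baseline
#'   noise sd (30).
#' @param dad_peak_sd Chromatographic peak sd in minutes (0.05).
#' @param intensity_jitter sdlog of the per-analog fragment intensity jitter
#'   (0.15).
#' @param viability_sd Gaussian viability noise sd in percent (5).
#' @param dma_noise_sd Absorbance noise sd for the DMA series (0.001).
#' @param dose_ladder Dose ladder in ug/mL.
#' @param n_dr_replicates Biological replicates of the dose-response (3).
#' @param true_yields data.frame(extract_id, blue, green): true relative
#'   singlet-oxygen yields in percent.
#' @param true_ec50 data.frame(extract_id, cell_line, light, ec50, hill).
#' @param aa_protection Fraction of DMA bleaching suppressed by ascorbate in
#'   the DMA+AA wells (0.3).
#' @return Object of class \code{generator_config}.
#' @export
generator_config <- function(seed,
                             family_plan = default_family_plan(),
                             extracts = c("callisteus", "traganus", "trivialis",
                                          "venetus", "rubrophyllus",
                                          "xanthophyllus"),
                             rt_spacing = 0.5,
                             specific_share = 0.995,
                             dad_noise_sd = 0.5,
                             dad_amp_snr = 30,
                             dad_peak_sd = 0.05,
                             intensity_jitter = 0.15,
                             viability_sd = 5,
                             dma_noise_sd = 0.001,
                             dose_ladder = c(37.5, 18.75, 7.5, 3.75, 1.875, 0.375),
                             n_dr_replicates = 3L,
                             true_yields = default_true_yields(),
                             true_ec50 = default_true_ec50(),
                             aa_protection = 0.3) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  stopifnot(all(family_plan$size > 0), all(family_plan$extract %in% extracts))
  n_bands_needed <- nrow(family_plan)
  if (n_bands_needed * 60 + 100 > 3000)
    stop("family plan exceeds the available m/z space", call. = FALSE)
  structure(list(seed = as.integer(seed), family_plan = family_plan,
                 extracts = extracts, rt_spacing = rt_spacing,
                 specific_share = specific_share, dad_noise_sd = dad_noise_sd,
                 dad_amp_snr = dad_amp_snr, dad_peak_sd = dad_peak_sd,
                 intensity_jitter = intensity_jitter,
                 viability_sd = viability_sd, dma_noise_sd = dma_noise_sd,
                 dose_ladder = dose_ladder,
                 n_dr_replicates = as.integer(n_dr_replicates),
                 true_yields = true_yields, true_ec50 = true_ec50,
                 aa_protection = aa_protection),
            class = "generator_config")
}

#' Generate fragment spectra for the planted compound families
#'
#' Each family owns a scaffold of 8-15 shared fragment peaks drawn from an
#' m/z band disjoint from every other family's (so between-family similarity
#' is ~0 by construction). Analogs apply one derivatization mass shift
#' (methylation +14.0157, oxidation +15.9949, glycosylation +162.0528, or
#' H-to-Cl +33.9610) to the precursor and to a fixed "substitution-site"
#' subset of the scaffold fragments, with log-normal intensity jitter per
#' analog -- so within-family modified cosine stays high while precursors
#' differ.
#'
#' @param config A \code{generator_config}.
#' @return List with \code{spectra} (list of \code{fragment_spectrum}),
#'   \code{families} (named character vector feature_id -> family), and
#'   \code{info} (data.frame of feature_id, family, rt, extract, chromophore,
#'   specific).
#' @export
generate_spectra <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  plan <- config$family_plan
  n_features <- sum(plan$size)
  rt_slots <- 0.5 + config$rt_spacing * (seq_len(n_features) - 1L)
  rt_order <- sample.int(n_features)
  spectra <- vector("list", n_features)
  info <- vector("list", nrow(plan))
  k <- 0L
  for (f in seq_len(nrow(plan))) {
    n_scaffold <- sample(8:15, 1L)
    band_lo <- 100 + (f - 1L) * 60
    scaffold_mz <- sort(band_lo + stats::runif(n_scaffold, 0, 50))
    base_int <- stats::rlnorm(n_scaffold, meanlog = log(100), sdlog = 1)
    precursor0 <- band_lo + 50 + 120 + stats::runif(1, 0, 40)
    n_shift_sites <- max(1L, round(n_scaffold * 0.3))
    sites <- sort(sample.int(n_scaffold, n_shift_sites))
    shifts <- c(0, sample(ANALOG_SHIFTS, plan$size[f] - 1L, replace = TRUE))
    fam_rows <- vector("list", plan$size[f])
    for (m in seq_len(plan$size[f])) {
      k <- k + 1L
      fid <- sprintf("F%03d", k)
      mz <- scaffold_mz
      mz[sites] <- mz[sites] + shifts[m]
      inten <- base_int * stats::rlnorm(n_scaffold, 0, config$intensity_jitter)
      o <- order(mz)
      rt <- rt_slots[rt_order[k]]
      spectra[[k]] <- fragment_spectrum(fid, precursor0 + shifts[m], rt = rt,
                                        peaks = cbind(mz[o], inten[o]))
      fam_rows[[m]] <- data.frame(feature_id = fid, family = plan$family[f],
                                  rt = rt, extract = plan$extract[f],
                                  chromophore = plan$chromophore[f],
                                  specific = plan$specific[f],
                                  stringsAsFactors = FALSE)
    }
    info[[f]] <- do.call(rbind, fam_rows)
  }
  info <- do.call(rbind, info)
  families <- stats::setNames(info$family, info$feature_id)
  list(spectra = spectra, families = families, info = info)
}

# Dirichlet draw via independent gammas.
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Generate the quantification table and DAD traces
#'
#' Peak areas realize the designed specificity: planned-specific features get
#' exactly \code{specific_share} (default 0.995) of their total area in their
#' target extract; other features get Dirichlet-distributed shares leaning
#' toward their majority extract, capped below 0.98. Chromophore features add
#' a Gaussian DAD peak (sd \code{dad_peak_sd} min) at their retention time in
#' their majority extract with amplitude \code{dad_amp_snr} x baseline noise;
#' non-chromophores add none.
#'
#' @param config A \code{generator_config}.
#' @param spectra_info The \code{info} data.frame from
#'   \code{\link{generate_spectra}}.
#' @return List with \code{table} (a \code{feature_table}) and \code{traces}
#'   (list of \code{dad_trace}, one per extract, 468 nm).
#' @export
generate_quant_and_dad <- function(config, spectra_info) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed + 1L)
  info <- spectra_info
  extracts <- config$extracts
  n <- nrow(info)
  areas <- matrix(0, n, length(extracts), dimnames = list(info$feature_id, extracts))
  for (i in seq_len(n)) {
    total <- stats::rlnorm(1, meanlog = log(1e6), sdlog = 0.5)
    target <- match(info$extract[i], extracts)
    if (info$specific[i]) {
      shares <- numeric(length(extracts))
      rest <- rdirichlet1(rep(1, length(extracts) - 1L))
      shares[-target] <- (1 - config$specific_share) * rest
      shares[target] <- config$specific_share
    } else {
      alpha <- rep(2, length(extracts))
      alpha[target] <- 8
      shares <- rdirichlet1(alpha)
      if (max(shares) > 0.98) {       # keep non-planted features below the
        top <- which.max(shares)      # complete-specificity level
        excess <- shares[top] - 0.95
        shares[top] <- 0.95
        shares[-top] <- shares[-top] + excess * rdirichlet1(rep(1, length(extracts) - 1L))
      }
    }
    areas[i, ] <- total * shares
  }
  features <- data.frame(feature_id = info$feature_id,
                         mz = if ("mz" %in% names(info)) info$mz else 0,
                         rt = info$rt, stringsAsFactors = FALSE)
  table <- feature_table(features, areas)
  rt_max <- max(info$rt) + 2
  grid <- seq(0, rt_max, by = 0.01)
  traces <- lapply(extracts, function(e) {
    ab <- 1 + stats::rnorm(length(grid), 0, config$dad_noise_sd)
    chrom <- info[info$chromophore & info$extract == e, , drop = FALSE]
    amp <- config$dad_amp_snr * config$dad_noise_sd
    for (j in seq_len(nrow(chrom)))
      ab <- ab + amp * exp(-(grid - chrom$rt[j])^2 / (2 * config$dad_peak_sd^2))
    dad_trace(e, 468, grid, ab)
  })
  names(traces) <- extracts
  list(table = table, traces = traces)
}

#' Generate DMA kinetics and dose-response tables
#'
#' DMA series decay exponentially, A377(t) = A0 exp(-k t) + noise, with the
#' sample rate proportional to its true relative yield times the positive
#' control's rate (berberine for blue light, rose bengal for green);
#' technical duplicates, a t = 0 read plus four irradiation cycles (5 min
#' blue, 4.6 min green). Ascorbate co-incubation wells decay at
#' (1 - aa_protection) x the DMA rate. Viability follows the Hill model at
#' the true EC50 and slope with Gaussian noise; dark conditions use a true
#' EC50 beyond the top tested dose, so their fits censor by design.
#'
#' @param config A \code{generator_config}.
#' @return List with \code{dma} (data.frame: extract_id, light, condition,
#'   replicate, time, a377) and \code{dose_response} (data.frame: extract_id,
#'   cell_line, light, replicate, concentration, viability).
#' @export
generate_assays <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed + 2L)
  # positive-control bleaching rate: chosen so every series, including samples
  # bleaching ~1.8x faster than the control, stays in the initial-slope linear
  # regime while remaining well above the absorbance noise floor
  k_control <- c(blue = 0.006, green = 0.006)
  cycles <- c(blue = 5, green = 4.6)
  controls <- c(blue = "berberine", green = "rose_bengal")
  dma_rows <- list()
  mk <- function(extract, light, condition, k) {
    t <- cycles[[light]] * 0:4
    do.call(rbind, lapply(1:2, function(rep) {
      data.frame(extract_id = extract, light = light, condition = condition,
                 replicate = rep, time = t,
                 a377 = exp(-k * t) + stats::rnorm(length(t), 0, config$dma_noise_sd),
                 stringsAsFactors = FALSE)
    }))
  }
  for (light in c("blue", "green")) {
    kc <- k_control[[light]]
    dma_rows[[length(dma_rows) + 1L]] <- mk(controls[[light]], light, "DMA", kc)
    dma_rows[[length(dma_rows) + 1L]] <- mk("blank", light, "blank", 0)
    for (i in seq_len(nrow(config$true_yields))) {
      e <- config$true_yields$extract_id[i]
      ks <- config$true_yields[[light]][i] / 100 * kc
      dma_rows[[length(dma_rows) + 1L]] <- mk(e, light, "DMA", ks)
      dma_rows[[length(dma_rows) + 1L]] <-
        mk(e, light, "DMA+AA", ks * (1 - config$aa_protection))
    }
  }
  dma <- do.call(rbind, dma_rows)
  rownames(dma) <- NULL
  dr_rows <- list()
  for (i in seq_len(nrow(config$true_ec50))) {
    row <- config$true_ec50[i, ]
    for (rep in seq_len(config$n_dr_replicates)) {
      viab <- 100 / (1 + (config$dose_ladder / row$ec50)^row$hill) +
        stats::rnorm(length(config$dose_ladder), 0, config$viability_sd)
      dr_rows[[length(dr_rows) + 1L]] <-
        data.frame(extract_id = row$extract_id, cell_line = row$cell_line,
                   light = row$light, replicate = rep,
                   concentration = config$dose_ladder, viability = viab,
                   stringsAsFactors = FALSE)
    }
  }
  dr <- do.call(rbind, dr_rows)
  rownames(dr) <- NULL
  list(dma = dma, dose_response = dr)
}

#' Generate the full in-memory dataset
#'
#' Convenience wrapper running all three generator stages; deterministic per
#' (seed, config).
#'
#' @param config A \code{generator_config}.
#' @return List with \code{spectra}, \code{families}, \code{info},
#'   \code{table}, \code{traces}, \code{dma}, \code{dose_response},
#'   \code{truth}.
#' @export
generate_dataset <- function(config) {
  sp <- generate_spectra(config)
  mz <- vapply(sp$spectra, `[[`, numeric(1), "precursor_mz")
  sp$info$mz <- mz
  qd <- generate_quant_and_dad(config, sp$info)
  assays <- generate_assays(config)
  truth <- list(
    families = as.list(sp$families),
    chromophore = as.list(stats::setNames(sp$info$chromophore, sp$info$feature_id)),
    specific = as.list(stats::setNames(sp$info$specific, sp$info$feature_id)),
    designed_extract = as.list(stats::setNames(sp$info$extract, sp$info$feature_id)),
    active_extracts = unique(c(
      config$true_yields$extract_id[config$true_yields$blue >= 5 |
                                      config$true_yields$green >= 5])),
    true_yields = config$true_yields,
    true_ec50 = config$true_ec50,
    specific_plan = as.list(table(sp$info$extract[sp$info$specific & sp$info$chromophore])))
  list(spectra = sp$spectra, families = sp$families, info = sp$info,
       table = qd$table, traces = qd$traces,
       dma = assays$dma, dose_response = assays$dose_response, truth = truth)
}

#' Write a complete input bundle to disk
#'
#' Emits every pipeline input format (MGF, feature-table CSV, one DAD CSV per
#' extract, DMA kinetics CSV, dose-response CSV), the ground-truth JSON, and
#' a manifest listing the files and seed. Byte-identical for identical
#' (seed, config).
#'
#' @param config A \code{generator_config}.
#' @param out_dir Output directory; must be empty or absent unless
#'   \code{force}.
#' @param force Overwrite a non-empty directory.
#' @return Invisibly, the manifest (list of file names + seed).
#' @export
generate_bundle <- function(config, out_dir, force = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0L && !force)
    stop("output directory is not empty (use force = TRUE): ", out_dir,
         call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ds <- generate_dataset(config)
  files <- character(0)
  p <- function(f) file.path(out_dir, f)
  write_mgf(ds$spectra, p("spectra.mgf")); files <- c(files, "spectra.mgf")
  write_feature_table(ds$table, p("feature_table.csv"))
  files <- c(files, "feature_table.csv")
  for (e in names(ds$traces)) {
    f <- sprintf("dad_%s.csv", e)
    write_dad_trace(ds$traces[[e]], p(f))
    files <- c(files, f)
  }
  utils::write.csv(ds$dma, p("dma_kinetics.csv"), row.names = FALSE, quote = FALSE)
  files <- c(files, "dma_kinetics.csv")
  utils::write.csv(ds$dose_response, p("dose_response.csv"), row.names = FALSE,
                   quote = FALSE)
  files <- c(files, "dose_response.csv")
  jsonlite::write_json(ds$truth, p("ground_truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- c(files, "ground_truth.json")
  manifest <- list(seed = config$seed, files = sort(c(files, "manifest.json")))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
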