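# End-to-end orchestration: read inputs, build the network, overlay the
# specificity and VIS-Signal variables, quantify extract photoactivity,
# annotate, rank clusters, and write the Cytoscape-ready artifacts plus a
# machine-readable run summary.

#' Pipeline configuration
#'
#' Collects all input paths and stage parameters. Paths may point at a bundle
#' written by \code{\link{generate_bundle}} (see \code{from_bundle}) or at any
#' files in the documented schemas.
#'
#' @param mgf Path to the MGF with one MS2 spectrum per feature.
#' @param feature_table Path to the aligned quantification CSV.
#' @param dad_traces Character vector of DAD trace CSV paths (one per
#'   extract).
#' @param dma Path to the DMA kinetics CSV (columns extract_id, light,
#'   condition, replicate, time, a377), or NULL to skip the assay stage.
#' @param dose_response Path to the dose-response CSV (columns extract_id,
#'   cell_line, light, replicate, concentration, viability), or NULL.
#' @param out_dir Output directory for the artifacts.
#' @param library Optional list of \code{library_entry} objects for
#'   annotation.
#' @param networking List of networking parameters (score_threshold,
#'   min_matched, top_k, max_component_size, frag_tol).
#' @param vis List of VIS-Signal parameters (wavelength_nm, rt_window_min,
#'   snr_threshold).
#' @param specificity_level Specificity level for candidate selection (0.99).
#' @param c_max Top tested dose for EC50 censoring in ug/mL (37.5).
#' @param dma_floor DMA activity floor in percent (5).
#' @param positive_controls Named map light -> control extract_id in the DMA
#'   table.
#' @param sample_taxonomy Named taxonomy vector for re-ranking, or NULL.
#' @param annotation_weights Rank weights for \code{\link{taxonomic_rerank}}.
#' @param seed Seed recorded in the summary (any stochastic restart draws).
#' @return Object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(mgf, feature_table, dad_traces,
                            dma = NULL, dose_response = NULL,
                            out_dir = tempfile("photonet_run"),
                            library = NULL,
                            networking = list(),
                            vis = list(),
                            specificity_level = 0.99,
                            c_max = 37.5,
                            dma_floor = 5,
                            positive_controls = c(blue = "berberine",
                                                  green = "rose_bengal"),
                            sample_taxonomy = NULL,
                            annotation_weights = c(species = 0.20,
                                                   genus = 0.10,
                                                   family = 0.05),
                            seed = 1L) {
  networking <- utils::modifyList(
    list(score_threshold = 0.7, min_matched = 6L, top_k = 10L,
         max_component_size = 100L, frag_tol = 0.02), networking)
  vis <- utils::modifyList(
    list(wavelength_nm = 468, rt_window_min = 0.1, snr_threshold = 3), vis)
  cfg <- list(mgf = mgf, feature_table = feature_table,
              dad_traces = dad_traces, dma = dma,
              dose_response = dose_response, out_dir = out_dir,
              library = library, networking = networking, vis = vis,
              specificity_level = specificity_level, c_max = c_max,
              dma_floor = dma_floor, positive_controls = positive_controls,
              sample_taxonomy = sample_taxonomy,
              annotation_weights = annotation_weights, seed = as.integer(seed))
  for (f in c(cfg$mgf, cfg$feature_table, cfg$dad_traces, cfg$dma,
              cfg$dose_response))
    if (!file.exists(f)) stop("input file not found: ", f, call. = FALSE)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Pipeline configuration from a generated bundle directory
#'
#' @param dir Directory written by \code{\link{generate_bundle}}.
#' @param ... Passed on to \code{\link{pipeline_config}}.
#' @return A \code{pipeline_config}.
#' @export
from_bundle <- function(dir, ...) {
  pipeline_config(
    mgf = file.path(dir, "spectra.mgf"),
    feature_table = file.path(dir, "feature_table.csv"),
    dad_traces = list.files(dir, pattern = "^dad_.*\\.csv$", full.names = TRUE),
    dma = file.path(dir, "dma_kinetics.csv"),
    dose_response = file.path(dir, "dose_response.csv"),
    ...)
}

# Stable hash of the configuration (paths excluded, parameters included) so
# reruns can be recognized; any parameter change changes the hash.
config_hash <- function(config) {
  params <- config[c("networking", "vis", "specificity_level", "c_max",
                     "dma_floor", "positive_controls", "annotation_weights",
                     "seed")]
  json <- jsonlite::toJSON(params, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(json), tmp)
  unname(tools::md5sum(tmp))
}

# DMA yields per extract x light from the kinetics table, relative to the
# light source's positive control.
compute_dma_yields <- function(dma, positive_controls) {
  out <- list()
  for (light in intersect(unique(dma$light), names(positive_controls))) {
    ctl_id <- positive_controls[[light]]
    sub <- dma[dma$light == light, , drop = FALSE]
    ctl <- sub[sub$extract_id == ctl_id & sub$condition == "DMA", , drop = FALSE]
    if (nrow(ctl) == 0L) {
      warning("no positive control (", ctl_id, ") for ", light, " light",
              call. = FALSE)
      next
    }
    blank <- sub[sub$condition == "blank", , drop = FALSE]
    if (nrow(blank) == 0L) blank <- NULL
    control_kin <- as_dma_kinetics(ctl)
    blank_kin <- if (!is.null(blank)) as_dma_kinetics(blank) else NULL
    for (e in setdiff(unique(sub$extract_id[sub$condition == "DMA"]), ctl_id)) {
      kin <- as_dma_kinetics(sub[sub$extract_id == e & sub$condition == "DMA", ])
      y <- dma_relative_yield(kin, control_kin, blank_kin)
      out[[length(out) + 1L]] <- data.frame(
        extract_id = e, light = light, yield = y$yield, se = y$se,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(extract_id = character(0), light = character(0),
                      yield = numeric(0), se = numeric(0)))
  do.call(rbind, out)
}

as_dma_kinetics <- function(df) {
  dma_kinetics(df$extract_id[1L], df$light[1L], df$condition[1L],
               df$time, df$a377, df$replicate)
}

# Hill fits per extract x cell line x light, pooled over replicate points.
compute_ec50_table <- function(dr, c_max) {
  groups <- unique(dr[, c("extract_id", "cell_line", "light")])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    sub <- dr[dr$extract_id == g$extract_id & dr$cell_line == g$cell_line &
                dr$light == g$light, , drop = FALSE]
    fit <- fit_hill(sub$concentration, sub$viability, c_max = c_max)
    data.frame(extract_id = g$extract_id, cell_line = g$cell_line,
               light = g$light, ec50 = fit$ec50, ci_lo = fit$ci95[1L],
               ci_hi = fit$ci95[2L], hill_slope = fit$hill_slope,
               censored = fit$censored,
               class = classify_photocytotoxicity(fit$ec50),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Selectivity indices for every extract x cell line with both a dark and an
# irradiated fit.
compute_selectivity <- function(ec50_table) {
  out <- list()
  irr <- ec50_table[ec50_table$light != "dark", , drop = FALSE]
  dark <- ec50_table[ec50_table$light == "dark", , drop = FALSE]
  for (i in seq_len(nrow(irr))) {
    d <- dark[dark$extract_id == irr$extract_id[i] &
                dark$cell_line == irr$cell_line[i], , drop = FALSE]
    if (nrow(d) == 0L) next
    si <- selectivity_index(list(ec50 = d$ec50[1L], censored = d$censored[1L]),
                            list(ec50 = irr$ec50[i]))
    out[[length(out) + 1L]] <- data.frame(
      extract_id = irr$extract_id[i], cell_line = irr$cell_line[i],
      light = irr$light[i], si = si$value, lower_bound = si$lower_bound,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(extract_id = character(0), cell_line = character(0),
                      light = character(0), si = numeric(0),
                      lower_bound = logical(0)))
  do.call(rbind, out)
}

#' Run the full prioritization pipeline
#'
#' Executes the analysis end to end: input parsing, molecular networking,
#' specificity and VIS-Signal overlays, DMA yields and EC50/selectivity
#' fitting, optional annotation with marker propagation, and cluster ranking.
#' Writes GraphML, node-attribute TSV, ranked-cluster TSV, candidate-feature
#' TSV and a summary JSON to the configured output directory. Deterministic
#' given identical inputs and configuration.
#'
#' @param config A \code{pipeline_config}.
#' @return Object of class \code{run_summary} (invisible file side-effects in
#'   \code{config$out_dir}).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  spectra <- read_mgf(config$mgf)
  table <- read_feature_table(config$feature_table)
  traces <- lapply(config$dad_traces, read_dad_trace)
  n_spectra <- length(spectra)
  # id-join: spectra without a quant-table row are excluded from networking
  keep <- vapply(spectra, function(s) s$feature_id %in% table$features$feature_id,
                 logical(1))
  if (any(!keep))
    message(sum(!keep), " spectra lack a feature-table row and were excluded")
  spectra <- spectra[keep]
  net <- do.call(build_network, c(list(spectra = spectra), config$networking))
  spec <- feature_specificity(table)
  vis <- assign_vis_flags(table, traces,
                          rt_window = config$vis$rt_window_min,
                          snr_threshold = config$vis$snr_threshold,
                          wavelength = config$vis$wavelength_nm)
  yields <- if (!is.null(config$dma))
    compute_dma_yields(utils::read.csv(config$dma, stringsAsFactors = FALSE),
                       config$positive_controls)
  else data.frame(extract_id = character(0), light = character(0),
                  yield = numeric(0), se = numeric(0))
  ec50_table <- if (!is.null(config$dose_response))
    compute_ec50_table(utils::read.csv(config$dose_response,
                                       stringsAsFactors = FALSE), config$c_max)
  else NULL
  selectivity <- if (!is.null(ec50_table)) compute_selectivity(ec50_table)
  else NULL
  activity <- flag_active_extracts(yields, ec50_table, dma_floor = config$dma_floor)
  hits <- NULL
  if (!is.null(config$library) && length(config$library) > 0L) {
    hit_list <- lapply(spectra, library_match, library = config$library,
                       frag_tol = config$networking$frag_tol)
    hits <- do.call(rbind, hit_list)
    if (!is.null(config$sample_taxonomy) && nrow(hits) > 0L)
      hits <- taxonomic_rerank(hits, config$sample_taxonomy,
                               config$annotation_weights)
    net <- propagate_markers(net, hits)
  }
  clusters <- score_clusters(net, vis, spec, activity,
                             level = config$specificity_level)
  candidates <- select_candidate_features(vis, spec, activity,
                                          level = config$specificity_level)
  # merge overlays onto the network nodes for export
  nodes <- net$nodes
  nodes$vis_signal <- vis$flag[match(nodes$feature_id, vis$feature_id)]
  nodes$vis_snr <- vis$snr[match(nodes$feature_id, vis$feature_id)]
  m <- match(nodes$feature_id, spec$feature_id)
  for (e in attr(spec, "extracts"))
    nodes[[paste0("share_", e)]] <- spec[[e]][m]
  nodes$max_share <- spec$max_share[m]
  nodes$max_extract <- spec$max_extract[m]
  if (!is.null(hits) && nrow(hits) > 0L) {
    best <- hits[!duplicated(hits$feature_id), , drop = FALSE]
    bm <- match(nodes$feature_id, best$feature_id)
    nodes$annotation <- best$name[bm]
    nodes$identification_level <- best$identification_level[bm]
  }
  net$nodes <- nodes
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$out_dir, f)
  write_graphml(net, p("network.graphml"))
  write_node_attributes(net, p("node_attributes.tsv"))
  utils::write.table(clusters, p("clusters.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(candidates, p("candidates.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  comp_sizes <- table(net$components)
  counts <- list(
    spectra_read = n_spectra,
    nodes = nrow(net$nodes),
    edges = nrow(net$edges),
    clusters = sum(comp_sizes > 1L),
    singletons = length(net$singletons),
    vis_positive = sum(vis$flag == 1L),
    specific_per_extract = as.list(count_specific_features(
      spec, config$specificity_level)),
    candidates_per_extract = as.list(table(candidates$extract)),
    n_candidates = nrow(candidates),
    active_extracts = activity$extract_id[activity$active])
  summary <- list(counts = counts,
                  clusters = clusters,
                  candidates = candidates,
                  yields = yields,
                  ec50 = ec50_table,
                  selectivity = selectivity,
                  activity = activity,
                  config_hash = config_hash(config),
                  seed = config$seed)
  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  class(summary) <- "run_summary"
  invisible(summary)
}

#' @export
print.run_summary <- function(x, ...) {
  c0 <- x$counts
  cat("photonet run summary\n")
  cat(sprintf("  spectra read: %d, nodes: %d, edges: %d, clusters: %d, singletons: %d\n",
              c0$spectra_read, c0$nodes, c0$edges, c0$clusters, c0$singletons))
  cat(sprintf("  VIS-positive features: %d, candidate features: %d\n",
              c0$vis_positive, c0$n_candidates))
  cat("  active extracts:", paste(c0$active_extracts, collapse = ", "), "\n")
  top <- x$clusters[!is.na(x$clusters$rank), , drop = FALSE]
  if (nrow(top) > 0L) {
    cat("  top clusters (id: priority):",
        paste(sprintf("%d: %d", utils::head(top$cluster_id, 5),
                      utils::head(top$priority, 5)), collapse = ", "), "\n")
  }
  invisible(x)
}
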