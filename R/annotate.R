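# Simplified dereplication: spectral-library matching (reusing the modified
# cosine), taxonomically informed re-ranking, and marker-compound propagation
# through network clusters.

#' Construct a spectral-library entry
#'
#' @param name Compound name.
#' @param spectrum A \code{fragment_spectrum}.
#' @param adduct Adduct label, e.g. \code{"[M-H]-"}.
#' @param taxonomy Named character vector of source-organism taxonomy, e.g.
#'   \code{c(family = "Cortinariaceae", genus = "Cortinarius")}; may be empty.
#' @param marker Logical; TRUE for marker compounds of known identity
#'   (identification level 1 on a precursor-matched hit).
#' @return Object of class \code{library_entry}.
#' @export
library_entry <- function(name, spectrum, adduct = "[M-H]-",
                          taxonomy = character(0), marker = FALSE) {
  stopifnot(inherits(spectrum, "fragment_spectrum"))
  structure(list(name = name, spectrum = spectrum, adduct = adduct,
                 taxonomy = taxonomy, marker = isTRUE(marker)),
            class = "library_entry")
}

#' Match a query spectrum against a spectral library
#'
#' Scores the query against every entry with the modified cosine (shifted
#' peak matching handles analog mass differences such as methylation or
#' glycosylation). Hits passing both thresholds are ranked by score.
#' Identification level is 1 for marker entries whose precursor also matches
#' within tolerance, otherwise 2 (putative annotation).
#'
#' @param spectrum Query \code{fragment_spectrum}.
#' @param library List of \code{library_entry} objects.
#' @param frag_tol Fragment tolerance in Thomson, default 0.02.
#' @param min_score Minimum modified-cosine score, default 0.7.
#' @param min_matched Minimum matched peaks, default 6.
#' @return data.frame of hits: \code{feature_id}, \code{name},
#'   \code{base_score}, \code{n_matched}, \code{tax_boost},
#'   \code{final_score}, \code{identification_level}, \code{marker},
#'   plus a \code{taxonomy} list-column.
#' @export
library_match <- function(spectrum, library, frag_tol = 0.02,
                          min_score = 0.7, min_matched = 6L) {
  empty <- data.frame(feature_id = character(0), name = character(0),
                      base_score = numeric(0), n_matched = integer(0),
                      tax_boost = numeric(0), final_score = numeric(0),
                      identification_level = integer(0), marker = logical(0),
                      stringsAsFactors = FALSE)
  empty$taxonomy <- list()
  if (length(library) == 0L) {
    warning("empty spectral library; no annotation possible", call. = FALSE)
    return(empty)
  }
  rows <- lapply(library, function(entry) {
    mc <- modified_cosine(spectrum, entry$spectrum, frag_tol)
    if (mc$score < min_score || mc$n_matched < min_matched) return(NULL)
    prec_match <- abs(entry$spectrum$precursor_mz - spectrum$precursor_mz) <= frag_tol
    level <- if (entry$marker && prec_match) 1L else 2L
    out <- data.frame(feature_id = spectrum$feature_id, name = entry$name,
                      base_score = mc$score, n_matched = mc$n_matched,
                      tax_boost = 0, final_score = mc$score,
                      identification_level = level, marker = entry$marker,
                      stringsAsFactors = FALSE)
    out$taxonomy <- list(entry$taxonomy)
    out
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  hits <- do.call(rbind, rows)
  hits[order(-hits$final_score, hits$name), , drop = FALSE]
}

#' Taxonomically informed re-ranking of annotation hits
#'
#' Adds a boost to each hit's score for every taxonomic rank at which the
#' candidate's source taxonomy matches the sample's, then re-sorts by the
#' boosted score (stable: ties keep their previous order). Candidates without
#' taxonomy get no boost.
#'
#' @param hits Hit table from \code{\link{library_match}}.
#' @param sample_taxonomy Named character vector for the analyzed sample,
#'   e.g. \code{c(family = "Cortinariaceae", genus = "Cortinarius",
#'   species = "xanthophyllus")}.
#' @param weights Named non-negative boosts per rank; defaults
#'   species 0.20, genus 0.10, family 0.05.
#' @return The hit table, re-scored and re-ordered (same multiset of hits).
#' @export
taxonomic_rerank <- function(hits, sample_taxonomy,
                             weights = c(species = 0.20, genus = 0.10,
                                         family = 0.05)) {
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  if (nrow(hits) == 0L) return(hits)
  boost <- vapply(hits$taxonomy, function(tax) {
    if (length(tax) == 0L) return(0)
    ranks <- intersect(names(weights), intersect(names(tax), names(sample_taxonomy)))
    sum(weights[ranks][tax[ranks] == sample_taxonomy[ranks]])
  }, numeric(1))
  hits$tax_boost <- boost
  hits$final_score <- hits$base_score + boost
  hits[order(-hits$final_score), , drop = FALSE]
}

#' Propagate marker-compound identities through network clusters
#'
#' Every node in a connected component that contains a level-1 marker hit is
#' tagged with the marker name(s); scores are unchanged. This encodes the
#' structural-relatedness assumption behind molecular networking: analogs
#' cluster with the identified marker.
#'
#' @param network A \code{molecular_network}.
#' @param hits Annotation hit table (rows with
#'   \code{identification_level == 1} drive the propagation).
#' @return The network with a \code{marker_family} column added to
#'   \code{nodes} (\code{NA} where no marker reaches the node).
#' @export
propagate_markers <- function(network, hits) {
  stopifnot(inherits(network, "molecular_network"))
  network$nodes$marker_family <- NA_character_
  if (nrow(hits) == 0L) return(network)
  lvl1 <- hits[hits$identification_level == 1L, , drop = FALSE]
  if (nrow(lvl1) == 0L) return(network)
  comp <- network$components
  for (cid in unique(comp[lvl1$feature_id[lvl1$feature_id %in% names(comp)]])) {
    markers <- sort(unique(lvl1$name[comp[lvl1$feature_id] == cid &
                                       lvl1$feature_id %in% names(comp)]))
    members <- names(comp)[comp == cid]
    network$nodes$marker_family[network$nodes$feature_id %in% members] <-
      paste(markers, collapse = ";")
  }
  network
}
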