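# Integration stage: combine assay summaries, VIS-Signal flags and
# specificity into extract activity calls, ranked candidate clusters, and a
# per-extract candidate feature list.

#' Flag photoactive extracts from the assay summaries
#'
#' An extract is active iff its relative singlet-oxygen yield reaches the
#' activity floor on any light source, or any irradiated EC50 falls in the
#' "high" or "very high" potency band. Extracts missing from either table are
#' treated as inactive with a warning.
#'
#' @param yields data.frame with columns \code{extract_id}, \code{light},
#'   \code{yield} (percent relative to the positive control).
#' @param cytotox Optional data.frame with columns \code{extract_id},
#'   \code{cell_line}, \code{light}, \code{ec50}, \code{censored}; dark rows
#'   are ignored for the activity call.
#' @param dma_floor Activity floor in percent, default 5 (yields below it are
#'   negligible).
#' @return data.frame with columns \code{extract_id}, \code{dma_active},
#'   \code{cytotox_active}, \code{active}.
#' @export
flag_active_extracts <- function(yields, cytotox = NULL, dma_floor = 5) {
  stopifnot(all(c("extract_id", "light", "yield") %in% names(yields)))
  ids <- unique(c(yields$extract_id,
                  if (!is.null(cytotox)) cytotox$extract_id))
  dma_active <- vapply(ids, function(e) {
    y <- yields$yield[yields$extract_id == e]
    if (length(y) == 0L) {
      warning("no DMA yield for extract ", e, "; treated as inactive",
              call. = FALSE)
      return(FALSE)
    }
    any(y >= dma_floor)
  }, logical(1))
  cyto_active <- vapply(ids, function(e) {
    if (is.null(cytotox)) return(FALSE)
    cc <- cytotox[cytotox$extract_id == e & cytotox$light != "dark" &
                    !cytotox$censored, , drop = FALSE]
    if (nrow(cc) == 0L) return(FALSE)
    any(classify_photocytotoxicity(cc$ec50) %in% c("high", "very high"))
  }, logical(1))
  data.frame(extract_id = ids, dma_active = unname(dma_active),
             cytotox_active = unname(cyto_active),
             active = unname(dma_active | cyto_active),
             stringsAsFactors = FALSE)
}

#' Score and rank network clusters as candidate photosensitizer families
#'
#' The priority of a cluster is the number of its nodes that are both
#' VIS-positive and specific (max share strictly above \code{level}) to an
#' active extract -- the testable codification of highlighting clusters whose
#' light-absorbing members are confined to the photoactive extracts. Ranking
#' is by priority descending, ties broken by the VIS-positive count, then by
#' cluster id; clusters with priority 0 are left unranked.
#'
#' @param network A \code{molecular_network}.
#' @param vis_flags data.frame from \code{\link{assign_vis_flags}}.
#' @param specificity A \code{feature_specificity} object.
#' @param activity data.frame from \code{\link{flag_active_extracts}}.
#' @param level Specificity level, default 0.99 (complete specificity).
#' @return data.frame with one row per cluster: \code{cluster_id},
#'   \code{n_nodes}, \code{n_vis_positive}, \code{n_active_specific},
#'   \code{priority}, \code{rank} (NA for priority 0).
#' @export
score_clusters <- function(network, vis_flags, specificity, activity,
                           level = 0.99) {
  stopifnot(inherits(network, "molecular_network"),
            inherits(specificity, "feature_specificity"))
  known <- attr(specificity, "extracts")
  if (!all(activity$extract_id %in% known))
    stop("activity table names extracts absent from the specificity records: ",
         paste(setdiff(activity$extract_id, known), collapse = ", "),
         call. = FALSE)
  active_extracts <- activity$extract_id[activity$active]
  cand <- select_candidate_features(vis_flags, specificity, activity, level)
  vis_pos <- vis_flags$feature_id[vis_flags$flag == 1L]
  comp <- network$components
  out <- do.call(rbind, lapply(sort(unique(comp)), function(cid) {
    members <- names(comp)[comp == cid]
    data.frame(cluster_id = cid, n_nodes = length(members),
               n_vis_positive = sum(members %in% vis_pos),
               n_active_specific = sum(members %in% cand$feature_id),
               stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    return(data.frame(cluster_id = integer(0), n_nodes = integer(0),
                      n_vis_positive = integer(0), n_active_specific = integer(0),
                      priority = integer(0), rank = integer(0)))
  out$priority <- out$n_active_specific
  o <- order(-out$priority, -out$n_vis_positive, out$cluster_id)
  out <- out[o, , drop = FALSE]
  out$rank <- NA_integer_
  ranked <- out$priority > 0L
  out$rank[ranked] <- seq_len(sum(ranked))
  rownames(out) <- NULL
  out
}

#' Select candidate photoactive features
#'
#' Features that absorb visible light (VIS flag 1) AND are specific above
#' \code{level} to an extract AND whose majority extract is photoactive.
#'
#' @inheritParams score_clusters
#' @return data.frame with columns \code{feature_id}, \code{extract}, grouped
#'   by extract (ordered by extract then feature id).
#' @export
select_candidate_features <- function(vis_flags, specificity, activity,
                                      level = 0.99) {
  stopifnot(inherits(specificity, "feature_specificity"))
  if (level <= 0 || level >= 1)
    stop("level must lie strictly between 0 and 1", call. = FALSE)
  active_extracts <- activity$extract_id[activity$active]
  vis_pos <- vis_flags$feature_id[vis_flags$flag == 1L]
  sel <- !specificity$degenerate &
    specificity$max_share > level &
    specificity$max_extract %in% active_extracts &
    specificity$feature_id %in% vis_pos
  out <- data.frame(feature_id = specificity$feature_id[sel],
                    extract = specificity$max_extract[sel],
                    stringsAsFactors = FALSE)
  out[order(out$extract, out$feature_id), , drop = FALSE]
}
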