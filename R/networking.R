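# Feature-based molecular networking: modified-cosine spectral similarity and
# GNPS-style graph construction (score/min-matched filter, mutual top-k rank
# filter, component-size splitting).

#' Enumerate candidate matched peak pairs between two spectra
#'
#' A peak pair matches either directly (|mz_a - mz_b| <= frag_tol) or shifted
#' by the precursor mass difference Delta = precursor_b - precursor_a
#' (|mz_a - (mz_b - Delta)| <= frag_tol). Each candidate carries the product of
#' the square-root-scaled intensities as its weight; a peak may appear in
#' several candidates (the one-to-one assignment happens in
#' \code{\link{modified_cosine}}).
#'
#' @param a,b \code{fragment_spectrum} objects.
#' @param frag_tol Fragment m/z tolerance in Thomson (> 0).
#' @return data.frame with columns \code{index_a}, \code{index_b},
#'   \code{weight}, \code{shifted}.
#' @export
match_peaks <- function(a, b, frag_tol = 0.02) {
  stopifnot(inherits(a, "fragment_spectrum"), inherits(b, "fragment_spectrum"))
  if (!is.numeric(frag_tol) || length(frag_tol) != 1L || frag_tol <= 0)
    stop("frag_tol must be a single positive number", call. = FALSE)
  empty <- data.frame(index_a = integer(0), index_b = integer(0),
                      weight = numeric(0), shifted = logical(0))
  na <- nrow(a$peaks); nb <- nrow(b$peaks)
  if (na == 0L || nb == 0L) return(empty)
  delta <- b$precursor_mz - a$precursor_mz
  mza <- a$peaks[, 1L]; mzb <- b$peaks[, 1L]
  wa <- sqrt(a$peaks[, 2L]); wb <- sqrt(b$peaks[, 2L])
  # all-pairs distance tests; spectra are small (tens of peaks)
  dm <- abs(outer(mza, mzb, "-"))
  direct <- dm <= frag_tol
  shifted <- abs(outer(mza, mzb - delta, "-")) <= frag_tol
  hit <- direct | shifted
  if (!any(hit)) return(empty)
  idx <- which(hit, arr.ind = TRUE)
  out <- data.frame(index_a = idx[, 1L], index_b = idx[, 2L],
                    weight = wa[idx[, 1L]] * wb[idx[, 2L]],
                    shifted = !direct[hit])
  out[order(out$index_a, out$index_b), , drop = FALSE]
}

# Greedy maximum-weight one-to-one assignment over candidate pairs:
# descending weight, ties broken by smaller (index_a, index_b).
greedy_assign <- function(cand) {
  if (nrow(cand) == 0L)
    return(cand[0L, , drop = FALSE])
  ord <- order(-cand$weight, cand$index_a, cand$index_b)
  cand <- cand[ord, , drop = FALSE]
  used_a <- logical(max(cand$index_a))
  used_b <- logical(max(cand$index_b))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ia <- cand$index_a[i]; ib <- cand$index_b[i]
    if (!used_a[ia] && !used_b[ib]) {
      keep[i] <- TRUE
      used_a[ia] <- TRUE
      used_b[ib] <- TRUE
    }
  }
  cand[keep, , drop = FALSE]
}

#' Modified-cosine similarity between two fragment spectra
#'
#' Candidate peak pairs (direct or precursor-shifted, see
#' \code{\link{match_peaks}}) are assigned one-to-one greedily by descending
#' weight; the summed assigned weight is normalized by the product of the
#' Euclidean norms of the square-root-scaled intensity vectors, giving a score
#' in [0, 1] that is symmetric in its arguments.
#'
#' @inheritParams match_peaks
#' @return List with \code{score} (unitless, [0,1]) and \code{n_matched}
#'   (number of assigned peak pairs).
#' @export
modified_cosine <- function(a, b, frag_tol = 0.02) {
  cand <- match_peaks(a, b, frag_tol)
  if (nrow(cand) == 0L) return(list(score = 0, n_matched = 0L))
  assigned <- greedy_assign(cand)
  norm_a <- sqrt(sum(a$peaks[, 2L]))
  norm_b <- sqrt(sum(b$peaks[, 2L]))
  if (norm_a == 0 || norm_b == 0) return(list(score = 0, n_matched = 0L))
  score <- sum(assigned$weight) / (norm_a * norm_b)
  list(score = min(score, 1), n_matched = nrow(assigned))
}

# Pairwise scored edges above threshold for a list of spectra.
score_all_pairs <- function(spectra, score_threshold, min_matched, frag_tol) {
  ids <- vapply(spectra, `[[`, character(1), "feature_id")
  n <- length(spectra)
  res <- vector("list", n * (n - 1L) %/% 2L)
  k <- 0L
  for (i in seq_len(max(n - 1L, 0L))) {
    for (j in seq.int(i + 1L, n)) {
      mc <- modified_cosine(spectra[[i]], spectra[[j]], frag_tol)
      if (mc$score >= score_threshold && mc$n_matched >= min_matched) {
        k <- k + 1L
        res[[k]] <- data.frame(
          feature_a = ids[i], feature_b = ids[j],
          score = mc$score, n_matched = mc$n_matched,
          delta_mz = spectra[[j]]$precursor_mz - spectra[[i]]$precursor_mz,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (k == 0L)
    return(data.frame(feature_a = character(0), feature_b = character(0),
                      score = numeric(0), n_matched = integer(0),
                      delta_mz = numeric(0)))
  do.call(rbind, res[seq_len(k)])
}

# Mutual top-k filter: keep an edge only if both endpoints rank it within
# their top_k highest-scoring incident edges (ties by the other endpoint id).
topk_filter <- function(edges, top_k) {
  if (nrow(edges) == 0L) return(edges)
  long <- rbind(
    data.frame(node = edges$feature_a, other = edges$feature_b,
               score = edges$score, edge = seq_len(nrow(edges)),
               stringsAsFactors = FALSE),
    data.frame(node = edges$feature_b, other = edges$feature_a,
               score = edges$score, edge = seq_len(nrow(edges)),
               stringsAsFactors = FALSE))
  keep_per_node <- tapply(seq_len(nrow(long)), long$node, function(rows) {
    o <- rows[order(-long$score[rows], long$other[rows])]
    long$edge[utils::head(o, top_k)]
  })
  counts <- table(unlist(keep_per_node))
  kept <- as.integer(names(counts)[counts == 2L])  # within top_k of BOTH ends
  edges[sort(kept), , drop = FALSE]
}

# Split oversized connected components by repeatedly removing the lowest-
# scoring edge of any component above the size cap (ties by lexicographic
# endpoint ids), relabelling components after each removal.
split_components <- function(ids, edges, max_component_size) {
  repeat {
    comp <- component_labels(ids, edges)
    sizes <- table(comp)
    big <- names(sizes)[sizes > max_component_size]
    if (length(big) == 0L) return(list(edges = edges, components = comp))
    in_big <- comp[edges$feature_a] %in% big
    cand <- which(in_big)
    o <- cand[order(edges$score[cand], edges$feature_a[cand], edges$feature_b[cand])]
    edges <- edges[-o[1L], , drop = FALSE]
  }
}

# Connected-component labels (integer, 1-based, stable: components numbered by
# the order of their lexicographically smallest member).
component_labels <- function(ids, edges) {
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (nrow(edges) > 0L)
    g <- igraph::add_edges(g, rbind(match(edges$feature_a, ids),
                                    match(edges$feature_b, ids)))
  memb <- igraph::components(g)$membership
  first <- tapply(ids, memb, min)
  new_label <- integer(length(first))
  new_label[order(first)] <- seq_along(first)
  out <- new_label[match(as.character(memb), names(first))]
  names(out) <- ids
  out
}

#' Build a feature-based molecular network
#'
#' Scores every spectrum pair with the modified cosine, then applies the
#' GNPS-style topology filters: (1) keep edges with score >=
#' \code{score_threshold} and matched peaks >= \code{min_matched}; (2) keep an
#' edge only if it ranks within the \code{top_k} highest-scoring edges of both
#' endpoints; (3) while any connected component exceeds
#' \code{max_component_size}, drop its lowest-scoring edge; (4) label connected
#' components. Nodes left without edges are singletons.
#'
#' @param spectra List of \code{fragment_spectrum} objects with unique
#'   feature ids.
#' @param score_threshold Minimum modified-cosine score, default 0.7.
#' @param min_matched Minimum matched peak pairs per edge, default 6.
#' @param top_k Mutual rank cutoff, default 10.
#' @param max_component_size Component size cap, default 100.
#' @param frag_tol Fragment tolerance in Thomson, default 0.02.
#' @return Object of class \code{molecular_network}: \code{nodes} (data.frame
#'   of feature_id, mz, rt, cluster_id), \code{edges} (scored edge table),
#'   \code{components} (named integer vector), \code{singletons} (feature ids).
#' @export
build_network <- function(spectra, score_threshold = 0.7, min_matched = 6L,
                          top_k = 10L, max_component_size = 100L,
                          frag_tol = 0.02) {
  ids <- vapply(spectra, `[[`, character(1), "feature_id")
  if (anyDuplicated(ids)) stop("duplicate feature ids among spectra", call. = FALSE)
  edges <- score_all_pairs(spectra, score_threshold, min_matched, frag_tol)
  edges <- topk_filter(edges, top_k)
  if (length(ids) > 0L) {
    sp <- split_components(ids, edges, max_component_size)
    edges <- sp$edges
    comp <- sp$components
  } else comp <- integer(0)
  degree <- table(c(edges$feature_a, edges$feature_b))
  singletons <- ids[!(ids %in% names(degree))]
  nodes <- data.frame(
    feature_id = ids,
    mz = vapply(spectra, `[[`, numeric(1), "precursor_mz"),
    rt = vapply(spectra, `[[`, numeric(1), "rt"),
    cluster_id = unname(comp[ids]),
    stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, components = comp,
                 singletons = singletons,
                 params = list(score_threshold = score_threshold,
                               min_matched = min_matched, top_k = top_k,
                               max_component_size = max_component_size,
                               frag_tol = frag_tol)),
            class = "molecular_network")
}

#' @export
print.molecular_network <- function(x, ...) {
  n_clusters <- length(unique(x$nodes$cluster_id[!(x$nodes$feature_id %in% x$singletons)]))
  cat(sprintf("<molecular_network> %d nodes, %d edges, %d clusters, %d singletons\n",
              nrow(x$nodes), nrow(x$edges), n_clusters, length(x$singletons)))
  invisible(x)
}

#' @export
summary.molecular_network <- function(object, ...) {
  comp_sizes <- table(object$components)
  cluster_sizes <- comp_sizes[comp_sizes > 1L]
  out <- list(n_nodes = nrow(object$nodes), n_edges = nrow(object$edges),
              n_clusters = length(cluster_sizes),
              n_singletons = length(object$singletons),
              cluster_sizes = as.integer(cluster_sizes))
  class(out) <- "summary.molecular_network"
  out
}

#' @export
print.summary.molecular_network <- function(x, ...) {
  cat(sprintf("Molecular network: %d nodes, %d edges\n", x$n_nodes, x$n_edges))
  cat(sprintf("  clusters (size > 1): %d, singletons: %d\n",
              x$n_clusters, x$n_singletons))
  if (length(x$cluster_sizes))
    cat("  cluster sizes:", paste(sort(x$cluster_sizes, decreasing = TRUE),
                                  collapse = " "), "\n")
  invisible(x)
}
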