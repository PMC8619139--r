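# The two prioritization variables overlaid on the network:
# per-feature extract specificity (peak-area shares) and the binary
# "VIS-Signal" flag derived from DAD absorbance at a visible wavelength.

#' Per-feature extract specificity
#'
#' For each feature the share of each extract is its LC peak area in that
#' extract divided by the summed peak area over all extracts. Features whose
#' total area is zero are flagged degenerate and get all-zero shares.
#'
#' @param table A \code{feature_table}.
#' @return Object of class \code{feature_specificity}: a data.frame with one
#'   row per feature (\code{feature_id}, one share column per extract,
#'   \code{max_share}, \code{max_extract}, \code{degenerate}).
#' @export
feature_specificity <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  totals <- rowSums(table$areas)
  shares <- table$areas / ifelse(totals > 0, totals, 1)
  shares[totals == 0, ] <- 0
  max_idx <- max.col(shares, ties.method = "first")
  out <- data.frame(feature_id = table$features$feature_id,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(shares, check.names = FALSE))
  out$max_share <- shares[cbind(seq_len(nrow(shares)), max_idx)]
  out$max_extract <- table$extracts[max_idx]
  out$max_extract[totals == 0] <- NA_character_
  out$degenerate <- totals == 0
  rownames(out) <- NULL
  structure(out, extracts = table$extracts,
            class = c("feature_specificity", "data.frame"))
}

#' Count extract-specific features at a specificity level
#'
#' Counts features whose maximum share strictly exceeds \code{level},
#' attributed to the extract holding that share. Levels of interest are 0.60
#' (major occurrence), 0.95 (virtual specificity) and 0.99 (complete
#' specificity). Degenerate (all-zero) features are excluded. Optionally the
#' count is restricted to a set of VIS-positive feature ids.
#'
#' @param records A \code{feature_specificity} object.
#' @param level Specificity level in (0, 1); strict inequality is applied.
#' @param restrict_to Optional character vector of feature ids (e.g. the
#'   VIS-positive ones); only these are counted.
#' @return Named integer vector, one count per extract.
#' @export
count_specific_features <- function(records, level, restrict_to = NULL) {
  stopifnot(inherits(records, "feature_specificity"))
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1)
    stop("level must lie strictly between 0 and 1", call. = FALSE)
  extracts <- attr(records, "extracts")
  sel <- !records$degenerate & records$max_share > level
  if (!is.null(restrict_to)) sel <- sel & records$feature_id %in% restrict_to
  counts <- table(factor(records$max_extract[sel], levels = extracts))
  out <- as.integer(counts)
  names(out) <- extracts
  out
}

#' VIS-Signal evidence for one feature
#'
#' Scans every extract's DAD trace for absorbance at the feature's retention
#' time: within +/- \code{rt_window} the peak height above a local baseline is
#' computed as the mean absorbance in the window minus the baseline (baseline
#' = median of the trace within +/- 5x \code{rt_window}, excluding the window
#' itself; the window mean is used rather than the window maximum so that
#' detector noise alone cannot mimic a peak), the noise is the median absolute
#' deviation of the baseline region (scaled by 1.4826), and
#' snr = height / noise. The flag is 1 iff the best snr across extracts
#' reaches \code{snr_threshold}.
#'
#' @param feature_rt Feature retention time in minutes.
#' @param traces List of \code{dad_trace} objects (one per extract).
#' @param rt_window Half-width of the search window in minutes, default 0.1.
#' @param snr_threshold Signal-to-noise threshold, default 3 (conventional
#'   detection limit); low-abundance chromophores below it stay flagged 0.
#' @return List with \code{flag} (0/1), \code{snr}, \code{source_extract}.
#' @export
extract_vis_signal <- function(feature_rt, traces, rt_window = 0.1,
                               snr_threshold = 3) {
  best <- list(flag = 0L, snr = 0, source_extract = NA_character_)
  for (tr in traces) {
    stopifnot(inherits(tr, "dad_trace"))
    in_win <- abs(tr$rt - feature_rt) <= rt_window
    if (!any(in_win)) {
      warning("no DAD points within the RT window for extract ", tr$extract_id,
              call. = FALSE)
      next
    }
    in_base <- abs(tr$rt - feature_rt) <= 5 * rt_window & !in_win
    if (!any(in_base)) in_base <- !in_win
    baseline <- stats::median(tr$absorbance[in_base])
    noise <- stats::mad(tr$absorbance[in_base], constant = 1.4826)
    height <- mean(tr$absorbance[in_win]) - baseline
    snr <- if (height <= 0) 0 else if (noise > 0) height / noise else Inf
    if (snr > best$snr)
      best <- list(flag = 0L, snr = snr, source_extract = tr$extract_id)
  }
  best$flag <- as.integer(best$snr >= snr_threshold)
  best
}

#' Assign VIS-Signal flags to every feature
#'
#' Applies \code{\link{extract_vis_signal}} to each feature of the table,
#' taking the best evidence across extracts. Deterministic. With no traces at
#' all, every flag is 0.
#'
#' @param table A \code{feature_table}.
#' @param traces List of \code{dad_trace} objects.
#' @param rt_window,snr_threshold See \code{\link{extract_vis_signal}}.
#' @param wavelength Expected DAD wavelength in nm (default 468); traces at a
#'   different wavelength are skipped with a warning.
#' @return data.frame with columns \code{feature_id}, \code{flag}, \code{snr},
#'   \code{source_extract}.
#' @export
assign_vis_flags <- function(table, traces, rt_window = 0.1,
                             snr_threshold = 3, wavelength = 468) {
  stopifnot(inherits(table, "feature_table"))
  use <- vapply(traces, function(tr) {
    ok <- isTRUE(all.equal(tr$wavelength, wavelength))
    if (!ok) warning("skipping DAD trace for ", tr$extract_id,
                     " at ", tr$wavelength, " nm (expected ", wavelength, " nm)",
                     call. = FALSE)
    ok
  }, logical(1))
  traces <- traces[use]
  res <- lapply(table$features$rt, function(rt)
    extract_vis_signal(rt, traces, rt_window, snr_threshold))
  data.frame(feature_id = table$features$feature_id,
             flag = vapply(res, `[[`, integer(1), "flag"),
             snr = vapply(res, `[[`, numeric(1), "snr"),
             source_extract = vapply(res, `[[`, character(1), "source_extract"),
             stringsAsFactors = FALSE)
}
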