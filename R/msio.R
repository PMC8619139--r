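# I/O for the external formats the pipeline consumes and emits:
# MGF fragment spectra, aligned feature quantification tables (CSV),
# DAD chromatogram traces (CSV), GraphML + node-attribute TSV for Cytoscape.
# All retention times are minutes, all m/z are Thomson, decimal separator ".".

#' Construct a fragment spectrum
#'
#' One MS2 scan tied to an aligned LC-MS feature. Peaks are stored as a
#' two-column matrix (mz, intensity) sorted by ascending m/z.
#'
#' @param feature_id Character scalar; unique feature identifier linking the
#'   spectrum to the quantification table (MZmine FBMN convention).
#' @param precursor_mz Precursor m/z in Thomson, > 0.
#' @param rt Retention time in minutes, >= 0.
#' @param peaks Numeric matrix or data.frame with columns mz and intensity;
#'   may have zero rows. Intensities must be >= 0.
#' @param charge Integer charge; defaults to -1 (negative ionization mode).
#' @return An object of class \code{fragment_spectrum}.
#' @export
fragment_spectrum <- function(feature_id, precursor_mz, rt = 0, peaks = NULL,
                              charge = -1L) {
  stopifnot(is.character(feature_id), length(feature_id) == 1L, nzchar(feature_id))
  if (!is.numeric(precursor_mz) || length(precursor_mz) != 1L || precursor_mz <= 0)
    stop("precursor_mz must be a single positive number", call. = FALSE)
  if (!is.numeric(rt) || length(rt) != 1L || rt < 0)
    stop("rt must be a single non-negative number", call. = FALSE)
  if (is.null(peaks)) peaks <- matrix(numeric(0), ncol = 2L)
  peaks <- as.matrix(peaks)
  if (ncol(peaks) != 2L) stop("peaks must have two columns (mz, intensity)", call. = FALSE)
  storage.mode(peaks) <- "double"
  colnames(peaks) <- c("mz", "intensity")
  if (nrow(peaks) > 0L) {
    peaks <- peaks[order(peaks[, 1L]), , drop = FALSE]
    if (any(diff(peaks[, 1L]) <= 0))
      stop("peak m/z values must be strictly increasing (no duplicate m/z)", call. = FALSE)
    if (any(peaks[, 2L] < 0)) stop("peak intensities must be >= 0", call. = FALSE)
  }
  structure(
    list(feature_id = feature_id, precursor_mz = as.numeric(precursor_mz),
         charge = as.integer(charge), rt = as.numeric(rt), peaks = peaks),
    class = "fragment_spectrum"
  )
}

#' @export
print.fragment_spectrum <- function(x, ...) {
  cat(sprintf("<fragment_spectrum> %s  precursor m/z %.4f  charge %d  RT %.2f min  %d peaks\n",
              x$feature_id, x$precursor_mz, x$charge, x$rt, nrow(x$peaks)))
  invisible(x)
}

#' Read an MGF file
#'
#' Parses Mascot generic format with BEGIN IONS / END IONS blocks. PEPMASS is
#' required per block; FEATURE_ID, SCANS or TITLE supplies the feature id (in
#' that order of preference); RTINSECONDS is converted to minutes. Blocks with
#' no peaks are kept as empty-peak spectra.
#'
#' @param path Path to an MGF file.
#' @return A list of \code{fragment_spectrum} objects.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("MGF file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends) || any(ends < begins))
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS in ", path, call. = FALSE)
  spectra <- vector("list", length(begins))
  for (b in seq_along(begins)) {
    block <- lines[(begins[b] + 1L):(ends[b] - 1L)]
    block <- block[nzchar(block)]
    is_kv <- grepl("=", block, fixed = TRUE)
    kv <- block[is_kv]
    keys <- toupper(sub("=.*$", "", kv))
    vals <- sub("^[^=]*=", "", kv)
    getval <- function(key) if (key %in% keys) vals[match(key, keys)] else NA_character_
    pepmass <- getval("PEPMASS")
    if (is.na(pepmass))
      stop(sprintf("malformed MGF block %d in %s: missing PEPMASS", b, path), call. = FALSE)
    precursor <- as.numeric(strsplit(pepmass, "[[:space:]]+")[[1L]][1L])
    fid <- getval("FEATURE_ID")
    if (is.na(fid)) fid <- getval("SCANS")
    if (is.na(fid)) fid <- getval("TITLE")
    if (is.na(fid)) fid <- as.character(b)
    charge_str <- getval("CHARGE")
    charge <- -1L
    if (!is.na(charge_str)) {
      n <- as.integer(sub("[+-]$", "", charge_str))
      if (grepl("-", charge_str, fixed = TRUE)) n <- -n
      charge <- n
    }
    rt <- getval("RTINSECONDS")
    rt <- if (is.na(rt)) 0 else as.numeric(rt) / 60
    peak_lines <- block[!is_kv]
    if (length(peak_lines) > 0L) {
      fields <- strsplit(peak_lines, "[[:space:]]+")
      peaks <- do.call(rbind, lapply(fields, function(f) as.numeric(f[1:2])))
      if (anyNA(peaks))
        stop(sprintf("malformed MGF block %d in %s: unparseable peak line", b, path),
             call. = FALSE)
    } else peaks <- NULL
    spectra[[b]] <- fragment_spectrum(fid, precursor, rt = rt, peaks = peaks,
                                      charge = charge)
  }
  spectra
}

#' Write spectra to an MGF file
#'
#' @param spectra List of \code{fragment_spectrum} objects.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (sp in spectra) {
    stopifnot(inherits(sp, "fragment_spectrum"))
    chg <- if (sp$charge < 0) sprintf("%d-", abs(sp$charge)) else sprintf("%d+", sp$charge)
    writeLines(c(
      "BEGIN IONS",
      paste0("FEATURE_ID=", sp$feature_id),
      sprintf("PEPMASS=%.6f", sp$precursor_mz),
      paste0("CHARGE=", chg),
      sprintf("RTINSECONDS=%.6f", sp$rt * 60)
    ), con)
    if (nrow(sp$peaks) > 0L)
      writeLines(sprintf("%.6f %.6f", sp$peaks[, 1L], sp$peaks[, 2L]), con)
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}

#' Construct a feature quantification table
#'
#' Aligned features x extracts matrix of LC peak areas with feature m/z and
#' retention time.
#'
#' @param features data.frame with columns \code{feature_id}, \code{mz},
#'   \code{rt}.
#' @param areas Numeric matrix, one row per feature, one column per extract;
#'   column names are the extract ids. Areas must be >= 0; NA reads as 0.
#' @return An object of class \code{feature_table}.
#' @export
feature_table <- function(features, areas) {
  stopifnot(is.data.frame(features),
            all(c("feature_id", "mz", "rt") %in% names(features)))
  features$feature_id <- as.character(features$feature_id)
  if (anyDuplicated(features$feature_id))
    stop("duplicate feature ids in feature table", call. = FALSE)
  areas <- as.matrix(areas)
  storage.mode(areas) <- "double"
  areas[is.na(areas)] <- 0
  if (nrow(areas) != nrow(features))
    stop("areas must have one row per feature", call. = FALSE)
  if (is.null(colnames(areas)) || anyDuplicated(colnames(areas)))
    stop("areas must have unique extract-id column names", call. = FALSE)
  if (any(areas < 0)) stop("negative peak areas are not allowed", call. = FALSE)
  rownames(areas) <- features$feature_id
  structure(list(features = features[, c("feature_id", "mz", "rt")],
                 extracts = colnames(areas), areas = areas),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d features x %d extracts (%s)\n",
              nrow(x$areas), ncol(x$areas),
              paste(utils::head(x$extracts, 4), collapse = ", ")))
  invisible(x)
}

#' Read a feature quantification table from CSV
#'
#' Expected header: \code{id, mz, rt} followed by one area column per extract.
#' Blank area cells are read as 0.
#'
#' @param path CSV file path.
#' @return A \code{feature_table}.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("feature table not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("id", "mz", "rt")
  if (!all(need %in% names(df)))
    stop("feature table must have columns id, mz, rt", call. = FALSE)
  extract_cols <- setdiff(names(df), need)
  if (length(extract_cols) == 0L) stop("feature table has no extract columns", call. = FALSE)
  areas <- as.matrix(df[, extract_cols, drop = FALSE])
  feature_table(data.frame(feature_id = as.character(df$id), mz = df$mz, rt = df$rt,
                           stringsAsFactors = FALSE),
                areas)
}

#' Write a feature quantification table to CSV
#'
#' @param table A \code{feature_table}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  df <- data.frame(id = table$features$feature_id,
                   mz = table$features$mz, rt = table$features$rt,
                   stringsAsFactors = FALSE, check.names = FALSE)
  df <- cbind(df, as.data.frame(table$areas, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a DAD chromatogram trace
#'
#' @param extract_id Extract identifier.
#' @param wavelength Detection wavelength in nm (468 targets the visible
#'   absorption screen).
#' @param rt Numeric vector of retention times in minutes, strictly increasing.
#' @param absorbance Numeric vector of absorbances in mAU, same length.
#' @return An object of class \code{dad_trace}.
#' @export
dad_trace <- function(extract_id, wavelength, rt, absorbance) {
  stopifnot(length(rt) == length(absorbance))
  if (length(rt) < 2L) stop("a DAD trace needs at least 2 points", call. = FALSE)
  if (any(diff(rt) <= 0))
    stop("DAD trace retention times must be strictly increasing", call. = FALSE)
  structure(list(extract_id = as.character(extract_id),
                 wavelength = as.numeric(wavelength),
                 rt = as.numeric(rt), absorbance = as.numeric(absorbance)),
            class = "dad_trace")
}

#' @export
print.dad_trace <- function(x, ...) {
  cat(sprintf("<dad_trace> %s @ %g nm, %d points, RT %.2f-%.2f min\n",
              x$extract_id, x$wavelength, length(x$rt), min(x$rt), max(x$rt)))
  invisible(x)
}

#' Read a DAD trace from CSV
#'
#' Two comment header lines carry the metadata
#' (\code{# extract_id=...}, \code{# wavelength_nm=...}), then a CSV body with
#' columns \code{rt, absorbance}.
#'
#' @param path CSV file path.
#' @return A \code{dad_trace}.
#' @export
read_dad_trace <- function(path) {
  if (!file.exists(path)) stop("DAD trace not found: ", path, call. = FALSE)
  hdr <- readLines(path, n = 2L)
  meta <- function(key) {
    line <- grep(paste0("^#\\s*", key, "="), hdr, value = TRUE)
    if (length(line) != 1L)
      stop("DAD trace header must carry ", key, ": ", path, call. = FALSE)
    sub(paste0("^#\\s*", key, "="), "", line)
  }
  extract_id <- meta("extract_id")
  wavelength <- as.numeric(meta("wavelength_nm"))
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("rt", "absorbance") %in% names(df)))
    stop("DAD trace body must have columns rt, absorbance", call. = FALSE)
  dad_trace(extract_id, wavelength, df$rt, df$absorbance)
}

#' Write a DAD trace to CSV
#'
#' @param trace A \code{dad_trace}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_dad_trace <- function(trace, path) {
  stopifnot(inherits(trace, "dad_trace"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(paste0("# extract_id=", trace$extract_id),
               sprintf("# wavelength_nm=%g", trace$wavelength),
               "rt,absorbance"), con)
  writeLines(sprintf("%.6f,%.6f", trace$rt, trace$absorbance), con)
  invisible(path)
}

# Assemble the igraph object mirroring a molecular_network, with all node and
# edge overlay attributes attached (Cytoscape reads these from GraphML).
network_to_igraph <- function(network) {
  stopifnot(inherits(network, "molecular_network"))
  nodes <- network$nodes
  g <- igraph::make_empty_graph(n = nrow(nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes$feature_id)
  for (col in setdiff(names(nodes), "feature_id"))
    g <- igraph::set_vertex_attr(g, col, value = nodes[[col]])
  if (nrow(network$edges) > 0L) {
    el <- rbind(match(network$edges$feature_a, nodes$feature_id),
                match(network$edges$feature_b, nodes$feature_id))
    g <- igraph::add_edges(g, as.vector(el))
    g <- igraph::set_edge_attr(g, "score", value = network$edges$score)
    g <- igraph::set_edge_attr(g, "n_matched", value = network$edges$n_matched)
    g <- igraph::set_edge_attr(g, "delta_mz", value = network$edges$delta_mz)
  }
  g
}

#' Export a molecular network to GraphML
#'
#' The file is loadable by Cytoscape; node attributes include m/z, RT,
#' VIS-Signal flag, per-extract specificity shares, cluster id, and any
#' annotation columns merged onto the nodes; edge attributes carry the
#' modified-cosine score, matched-peak count and precursor mass difference.
#'
#' @param network A \code{molecular_network} (see \code{\link{build_network}}).
#' @param path Output GraphML path.
#' @return Invisibly, \code{path}.
#' @export
write_graphml <- function(network, path) {
  g <- network_to_igraph(network)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read back an exported GraphML network
#'
#' Round-trip companion of \code{\link{write_graphml}}; returns the igraph
#' object with all attributes.
#'
#' @param path GraphML path.
#' @return An igraph graph.
#' @export
read_graphml <- function(path) {
  if (!file.exists(path)) stop("GraphML file not found: ", path, call. = FALSE)
  igraph::read_graph(path, format = "graphml")
}

#' Export node attributes as a Cytoscape-importable TSV
#'
#' @param network A \code{molecular_network}.
#' @param path Output TSV path.
#' @return Invisibly, \code{path}.
#' @export
write_node_attributes <- function(network, path) {
  stopifnot(inherits(network, "molecular_network"))
  utils::write.table(network$nodes, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
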