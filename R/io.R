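# Tabular I/O. One dialect everywhere: tab-separated UTF-8 with a header
# line; "NA" or the empty string denote missing values.

read_tsv_checked <- function(path, required = NULL, what = "table") {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(nf) == 0L) stop(what, " file is empty: ", path)
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop(sprintf("%s file %s: line %d has %d fields, expected %d",
                 what, path, bad, nf[bad], nf[1L]))
  }
  df <- read.delim(path, sep = "\t", header = TRUE, quote = "",
                   na.strings = c("NA", ""), check.names = FALSE,
                   stringsAsFactors = FALSE, comment.char = "")
  if (!is.null(required)) {
    miss <- setdiff(required, names(df))
    if (length(miss))
      stop(sprintf("%s file %s: missing required column(s): %s",
                   what, path, paste(miss, collapse = ", ")))
  }
  df
}

#' Read a CpG probe manifest
#'
#' The manifest lists one row per array probe with its genomic location and
#' whether the probe is annotated to an enhancer element. Positions are
#' 1-based CpG coordinates as in array manifests; they are kept 1-based in
#' the returned table and converted to 0-based half-open intervals by the
#' region/promoter constructors.
#'
#' @param path TSV with header columns `probe_id`, `chrom`, `position`,
#'   `is_enhancer`.
#' @return data.frame with columns `probe_id` (character, unique), `chrom`
#'   (character), `position` (integer, >= 1), `is_enhancer` (logical).
#' @export
read_probe_manifest <- function(path) {
  df <- read_tsv_checked(path, c("probe_id", "chrom", "position", "is_enhancer"),
                         "probe manifest")
  pos <- suppressWarnings(as.integer(df$position))
  bad <- which(is.na(pos) & !is.na(df$position))
  if (length(bad))
    stop(sprintf("probe manifest %s: non-integer position %s on line %d",
                 path, dQuote(df$position[bad[1L]]), bad[1L] + 1L))
  if (anyNA(pos))
    stop(sprintf("probe manifest %s: missing position on line %d",
                 path, which(is.na(pos))[1L] + 1L))
  out <- data.frame(probe_id = as.character(df$probe_id),
                    chrom = as.character(df$chrom),
                    position = pos,
                    is_enhancer = parse_logical(df$is_enhancer, path),
                    stringsAsFactors = FALSE)
  validate_probe_manifest(out)
  out
}

parse_logical <- function(x, path) {
  v <- rep(NA, length(x))
  v[x %in% c("TRUE", "True", "true", "1", "T", TRUE)]   <- TRUE
  v[x %in% c("FALSE", "False", "false", "0", "F", FALSE)] <- FALSE
  if (anyNA(v))
    stop(sprintf("%s: non-logical is_enhancer value %s on line %d",
                 path, dQuote(as.character(x[which(is.na(v))[1L]])),
                 which(is.na(v))[1L] + 1L))
  as.logical(v)
}

validate_probe_manifest <- function(m) {
  dup <- m$probe_id[duplicated(m$probe_id)]
  if (length(dup))
    stop("duplicated probe_id in manifest: ", paste(unique(dup), collapse = ", "))
  if (any(m$position < 1L)) stop("probe positions must be >= 1 (1-based)")
  if (any(!nzchar(m$chrom)) || anyNA(m$chrom)) stop("empty chrom in manifest")
  invisible(m)
}

#' Read / write a numeric matrix with row and column identifiers
#'
#' First column holds the row identifier, the header line holds the sample
#' (column) identifiers. Empty cells and `"NA"` are read as missing.
#'
#' @param path TSV file path.
#' @return numeric matrix with dimnames; missing cells are `NA`.
#' @export
read_matrix <- function(path) {
  df <- read_tsv_checked(path, what = "matrix")
  if (ncol(df) < 2L) stop("matrix file needs a row-id column plus >= 1 sample")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicated row ids in matrix: ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    m2 <- suppressWarnings(apply(df[, -1L, drop = FALSE], 2L, as.numeric))
    nonnum <- is.na(m2) & !is.na(as.matrix(df[, -1L, drop = FALSE]))
    if (any(nonnum)) {
      idx <- which(nonnum, arr.ind = TRUE)[1L, ]
      stop(sprintf("matrix %s: non-numeric value on line %d, column %s",
                   path, idx[1L] + 1L, names(df)[idx[2L] + 1L]))
    }
    m <- m2
    if (is.null(dim(m))) m <- matrix(m, nrow = nrow(df))
  }
  storage.mode(m) <- "double"
  rownames(m) <- ids
  colnames(m) <- names(df)[-1L]
  if (anyDuplicated(colnames(m))) stop("duplicated column ids in matrix: ", path)
  m
}

#' @rdname read_matrix
#' @param m numeric matrix with dimnames.
#' @param id_name header used for the row-identifier column.
#' @export
write_matrix <- function(m, path, id_name = "feature_id") {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_name
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read an interaction edge list
#'
#' Generic reader for two-or-more-column interaction tables (lncRNA-miRNA,
#' miRNA-mRNA, drug-lncRNA-direction, ...). Duplicate rows (over the
#' expected columns) are dropped, keeping the first occurrence; the number
#' dropped is reported as a message and attached as attribute `n_dropped`.
#'
#' @param path TSV file path.
#' @param expected_columns character vector of required column names.
#' @return data.frame restricted to `expected_columns`, de-duplicated.
#' @export
read_edge_list <- function(path, expected_columns) {
  df <- read_tsv_checked(path, expected_columns, "edge list")
  df <- df[, expected_columns, drop = FALSE]
  for (j in seq_along(df)) if (!is.numeric(df[[j]])) df[[j]] <- as.character(df[[j]])
  dup <- duplicated(df)
  if (any(dup))
    message(sum(dup), " duplicate edge(s) dropped from ", basename(path))
  out <- df[!dup, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(dup)
  out
}

#' @rdname read_edge_list
#' @param edges data.frame of edges.
#' @export
write_edge_list <- function(edges, path) {
  write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read a gene model table
#'
#' @param path TSV with header columns `gene_id`, `gene_type`, `chrom`,
#'   `strand`, `tss`. `gene_type` must be `lncRNA` or `mRNA`; `strand` must
#'   be `+` or `-`; `tss` is the 1-based transcription start site.
#' @return validated data.frame.
#' @export
read_gene_models <- function(path) {
  df <- read_tsv_checked(path, c("gene_id", "gene_type", "chrom", "strand", "tss"),
                         "gene model")
  df$gene_id <- as.character(df$gene_id)
  df$gene_type <- as.character(df$gene_type)
  df$chrom <- as.character(df$chrom)
  df$strand <- as.character(df$strand)
  df$tss <- suppressWarnings(as.integer(df$tss))
  if (anyDuplicated(df$gene_id))
    stop("duplicated gene_id in ", path)
  if (!all(df$gene_type %in% c("lncRNA", "mRNA")))
    stop("gene_type must be 'lncRNA' or 'mRNA' in ", path)
  if (!all(df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-' in ", path)
  if (anyNA(df$tss) || any(df$tss < 1L))
    stop("tss must be a 1-based integer in ", path)
  df[, c("gene_id", "gene_type", "chrom", "strand", "tss")]
}

#' Read a survival table
#'
#' @param path TSV with header columns `sample_id`, `time`, `event`
#'   (0/1 or FALSE/TRUE).
#' @return data.frame with positive numeric `time` and integer `event`.
#' @export
read_survival_table <- function(path) {
  df <- read_tsv_checked(path, c("sample_id", "time", "event"), "survival")
  df$sample_id <- as.character(df$sample_id)
  df$time <- as.numeric(df$time)
  df$event <- as.integer(as.logical(as.numeric(df$event)) | FALSE)
  if (anyDuplicated(df$sample_id)) stop("duplicated sample_id in ", path)
  if (anyNA(df$time) || any(df$time <= 0)) stop("time must be > 0 in ", path)
  df[, c("sample_id", "time", "event")]
}

#' Write enhancer regions as a BED file
#'
#' Regions carry 0-based half-open coordinates, so they map onto BED
#' columns directly. Output is sorted by chromosome then start.
#'
#' @param regions data.frame with columns `region_id`, `chrom`, `start`,
#'   `end` (as from [build_enhancer_regions()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  stopifnot(all(c("region_id", "chrom", "start", "end") %in% names(regions)))
  if (any(regions$start >= regions$end))
    stop("invalid region: start >= end for ",
         regions$region_id[which(regions$start >= regions$end)[1L]])
  ord <- order(regions$chrom, regions$start)
  bed <- regions[ord, c("chrom", "start", "end", "region_id")]
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write gene sets in GMT format
#'
#' One set per line: set name, description, then member gene ids, all
#' tab-separated.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(parts, length, 1L) < 3L)
  if (length(short))
    stop(sprintf("GMT %s: line %d has fewer than 3 fields", path, short[1L]))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(names(sets))) stop("duplicated set names in ", path)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param descriptions optional character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(nm, d, g) paste(c(nm, d, g), collapse = "\t"),
                  names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Export a network as GraphML and/or edge-list TSV
#'
#' @param network an `emtrn_network` (list with `nodes` and `edges`
#'   data.frames) as produced by [assemble_emtrn()] or
#'   [build_drug_network()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(network, path) {
  nodes <- network$nodes
  edges <- network$edges
  g <- igraph::graph_from_data_frame(
    d = if (nrow(edges)) edges else data.frame(from = character(), to = character()),
    directed = FALSE, vertices = nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
write_network_tsv <- function(network, path) {
  write_edge_list(network$edges, path)
}
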