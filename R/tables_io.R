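# Readers/writers for the plain-text formats consumed and produced by the
# pipeline.  TSV is the canonical dialect (UTF-8, header row); CSV via sep.

.AA20 <- "ACDEFGHIKLMNPQRSTVWY"

#' Normalize identifiers for set operations
#'
#' Gene and protein identifiers are compared case-insensitively throughout the
#' package (sources mix human and mouse symbol conventions); the original
#' spelling is preserved in reports.
#'
#' @param x character vector of identifiers.
#' @return upper-cased, whitespace-trimmed identifiers.
#' @export
normalizeIds <- function(x) toupper(trimws(as.character(x)))

#' Read a peptide-level intensity table
#'
#' Expects a TSV with columns \code{peptide_sequence}, \code{protein_id},
#' \code{gene_symbol} followed by one intensity column per sample, plus a
#' sample-metadata TSV with columns \code{sample_id}, \code{group}
#' (\code{bait}/\code{control}) and \code{replicate}.  Empty cells become
#' missing values (\code{NA}), never zero.
#'
#' @param path peptide table file.
#' @param metadata_path sample metadata file.
#' @param sep field separator (default tab; use \code{","} for CSV).
#' @param validate_sequences check amino-acid alphabet (default \code{TRUE}).
#' @return A \linkS4class{PeptideExperiment}.
#' @export
readPeptideTable <- function(path, metadata_path, sep = "\t",
                             validate_sequences = TRUE) {
  tab <- read.delim(path, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop("empty peptide table: ", path)
  need <- c("peptide_sequence", "protein_id", "gene_symbol")
  if (!all(need %in% colnames(tab)))
    stop("peptide table must have columns ", paste(need, collapse = ", "))
  meta <- read.delim(metadata_path, sep = sep, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group", "replicate") %in% colnames(meta)))
    stop("metadata must have columns sample_id, group, replicate")
  sample_cols <- setdiff(colnames(tab), need)
  unknown <- setdiff(sample_cols, meta$sample_id)
  if (length(unknown))
    stop("sample column(s) absent from metadata: ",
         paste(unknown, collapse = ", "))
  absent <- setdiff(meta$sample_id, sample_cols)
  if (length(absent))
    stop("metadata sample(s) absent from table: ",
         paste(absent, collapse = ", "))
  x <- as.matrix(tab[, meta$sample_id, drop = FALSE])
  storage.mode(x) <- "double"
  if (any(x < 0, na.rm = TRUE)) stop("negative intensity in ", path)
  samples <- data.frame(group = meta$group, replicate = meta$replicate,
                        row.names = meta$sample_id)
  PeptideExperiment(x, tab[, need], samples,
                    validate_sequences = validate_sequences)
}

#' Write a peptide table and its sample metadata
#'
#' Inverse of \code{\link{readPeptideTable}}; missing values are written as
#' empty cells.
#'
#' @param x a \linkS4class{PeptideExperiment}.
#' @param path,metadata_path output files.
#' @param sep field separator.
#' @return invisibly, \code{path}.
#' @export
writePeptideTable <- function(x, path, metadata_path, sep = "\t") {
  tab <- data.frame(as.data.frame(rowData(x)),
                    as.data.frame(assay(x, "intensity")),
                    check.names = FALSE)
  write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE,
              na = "")
  meta <- data.frame(sample_id = colnames(x),
                     group = colData(x)$group,
                     replicate = colData(x)$replicate)
  write.table(meta, metadata_path, sep = sep, quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a gene/protein list (one identifier per line)
#'
#' Lines starting with \code{#} are comments.  Duplicates are collapsed
#' case-insensitively, keeping the first spelling seen.
#'
#' @param path plain-text file.
#' @return character vector of unique members (possibly empty, with a
#'   warning).
#' @export
readGeneList <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- lines[!duplicated(normalizeIds(lines))]
  if (length(out) == 0L)
    warning("gene list is empty after comment stripping: ", path)
  out
}

#' Write a gene list
#'
#' @param x character vector of identifiers.
#' @param path output file.
#' @param name optional set name written as a \code{#} comment header.
#' @return invisibly, \code{path}.
#' @export
writeGeneList <- function(x, path, name = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(name)) writeLines(paste("#", name), con)
  writeLines(x, con)
  invisible(path)
}

#' Read an interaction edge list
#'
#' Accepts two-column TSV (node, node) or three-column SIF (node, relation,
#' node; the relation is ignored).  Edge direction is ignored, self-loops are
#' dropped with a warning and duplicate edges are collapsed: the result is a
#' simple undirected \code{igraph} graph.
#'
#' @param path edge list file.
#' @param sep field separator.
#' @return an \code{igraph} object.
#' @export
readEdgeList <- function(path, sep = "\t") {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, sep, fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2L))
    stop("edge list row with fewer than 2 fields: line ",
         which(nf < 2L)[1L])
  ends <- t(vapply(parts, function(p) {
    if (length(p) >= 3L) c(p[1L], p[3L]) else c(p[1L], p[2L])
  }, character(2)))
  self <- ends[, 1L] == ends[, 2L]
  if (any(self)) {
    warning("dropped ", sum(self), " self-loop(s)")
    ends <- ends[!self, , drop = FALSE]
  }
  g <- igraph::graph_from_edgelist(ends, directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Write an interaction graph as a two-column edge list
#'
#' @param g an \code{igraph} object.
#' @param path output file.
#' @param sep field separator.
#' @return invisibly, \code{path}.
#' @export
writeEdgeList <- function(g, path, sep = "\t") {
  e <- igraph::as_edgelist(g)
  write.table(e, path, sep = sep, quote = FALSE, row.names = FALSE,
              col.names = c("node1", "node2"))
  invisible(path)
}

#' Read an FPKM expression matrix
#'
#' First column = gene identifier, remaining columns = samples (header row
#' gives sample ids).  Values must be non-negative.
#'
#' @param path expression matrix TSV.
#' @param sep field separator.
#' @return numeric matrix, genes x samples.
#' @export
readExpressionMatrix <- function(path, sep = "\t") {
  tab <- read.delim(path, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- tab[[1L]]
  if (any(m < 0, na.rm = TRUE)) stop("negative FPKM in ", path)
  m
}

#' Write an FPKM expression matrix
#'
#' @param m numeric matrix, genes x samples.
#' @param path output file.
#' @param sep field separator.
#' @return invisibly, \code{path}.
#' @export
writeExpressionMatrix <- function(m, path, sep = "\t") {
  tab <- data.frame(gene = rownames(m), m, check.names = FALSE)
  write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a FRAP recovery trace
#'
#' Expects columns \code{time_s} and \code{intensity} (or the first two
#' columns when unnamed).
#'
#' @param path trace TSV.
#' @param sep field separator.
#' @return data.frame with columns \code{time}, \code{intensity}.
#' @export
readFrapTrace <- function(path, sep = "\t") {
  tab <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  tcol <- if ("time_s" %in% colnames(tab)) "time_s" else colnames(tab)[1L]
  icol <- if ("intensity" %in% colnames(tab)) "intensity" else
    colnames(tab)[2L]
  data.frame(time = as.numeric(tab[[tcol]]),
             intensity = as.numeric(tab[[icol]]))
}
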