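# The core selection procedure: peptide-to-protein rollup, single-peptide
# exclusion, equal-variance t-test on log2 intensities, and joint
# fold-change / P-value hit selection.

#' Roll peptide intensities up to proteins
#'
#' Per-sample protein intensity is the sum of the protein's observed peptide
#' intensities in that sample; a protein cell is missing (\code{NA}) only when
#' every one of its peptides is missing there.  \code{n_peptides} counts
#' distinct peptide sequences assigned to the protein.  Peptides without a
#' protein assignment are not silently dropped: they are collected in
#' \code{metadata(result)$unassigned} with a warning.
#'
#' @param x a \linkS4class{PeptideExperiment}.
#' @return a \linkS4class{ProteinQuant} with the same samples.
#' @export
setGeneric("rollupPeptides", function(x) standardGeneric("rollupPeptides"))

#' @rdname rollupPeptides
setMethod("rollupPeptides", "PeptideExperiment", function(x) {
  rd <- rowData(x)
  unassigned <- is.na(rd$protein_id) | !nzchar(as.character(rd$protein_id))
  meta_un <- DataFrame()
  if (any(unassigned)) {
    warning(sum(unassigned),
            " peptide(s) without protein assignment routed to ",
            "metadata()$unassigned")
    meta_un <- rd[unassigned, , drop = FALSE]
    x <- x[!unassigned, ]
    rd <- rowData(x)
  }
  pid <- as.character(rd$protein_id)
  intens <- assay(x, "intensity")
  keep_order <- unique(pid)
  f <- factor(pid, levels = keep_order)
  summed <- rowsum(ifelse(is.na(intens), 0, intens), f)
  n_obs <- rowsum((!is.na(intens)) + 0L, f)
  summed[n_obs == 0L] <- NA_real_
  n_pep <- vapply(split(as.character(rd$peptide_sequence), f),
                  function(s) length(unique(s)), integer(1))
  gene <- vapply(split(as.character(rd$gene_symbol), f),
                 function(g) g[1L], character(1))
  out <- SummarizedExperiment(
    assays = list(intensity = summed),
    rowData = DataFrame(protein_id = keep_order,
                        gene_symbol = unname(gene[keep_order]),
                        n_peptides = unname(n_pep[keep_order])),
    colData = colData(x))
  out <- new("ProteinQuant", out)
  metadata(out)$unassigned <- meta_un
  out
})

#' Exclude single-peptide identifications
#'
#' Retains proteins identified by at least \code{min_peptides} distinct
#' peptide sequences (row order preserved).
#'
#' @param x a \linkS4class{ProteinQuant}.
#' @param min_peptides minimum distinct peptides (default 2, i.e. drop
#'   single-peptide identifications).
#' @return the filtered \linkS4class{ProteinQuant}.
#' @export
filterSinglePeptide <- function(x, min_peptides = 2L) {
  stopifnot(is(x, "ProteinQuant"), min_peptides >= 1L)
  x[rowData(x)$n_peptides >= min_peptides, ]
}

#' Test bait-vs-control enrichment per protein
#'
#' Runs a two-sided Student's (equal-variance, the default) or Welch t-test
#' on log2-transformed protein intensities, bait against control.  The fold
#' change is the ratio of raw group means, taken after the missing-value
#' policy is applied; \code{log2fc = log2(fold_change)}.  A protein is
#' \code{selected} when \code{fold_change >= fc_min} and
#' \code{p_value < p_max}.
#'
#' Missing-value policy: with \code{impute = "floor"} (default) missing cells
#' — and measured values below the floor, including zeros — are replaced by
#' \code{floor_factor} times the smallest nonzero observed intensity, applied
#' identically to both groups, which keeps bait-only proteins testable with a
#' finite fold change.  With \code{impute = "exclude"} missing cells are
#' dropped; a group left with fewer than two values makes the protein
#' \code{untestable} (\code{NA} p-value, never selected).
#'
#' @param x a \linkS4class{ProteinQuant} (run \code{\link{addIbaq}} first to
#'   carry delta-iBAQ into the results).
#' @param fc_min fold-change threshold, inclusive (default 10).
#' @param p_max P-value threshold, exclusive (default 0.001).
#' @param impute \code{"floor"} (default) or \code{"exclude"}.
#' @param floor_factor multiplier on the global minimum nonzero intensity
#'   (default 0.5).
#' @param var_equal pooled-variance Student's test (default \code{TRUE});
#'   \code{FALSE} for Welch.
#' @return an \linkS4class{EnrichmentResults} with one row per protein and a
#'   Benjamini-Hochberg \code{q_value} column reported alongside the raw
#'   P-values used for selection.
#' @export
setGeneric("testEnrichment", function(x, ...)
  standardGeneric("testEnrichment"))

#' @rdname testEnrichment
#' @param ... passed between methods.
setMethod("testEnrichment", "ProteinQuant", function(
    x, fc_min = 10, p_max = 0.001, impute = c("floor", "exclude"),
    floor_factor = 0.5, var_equal = TRUE) {
  impute <- match.arg(impute)
  stopifnot(fc_min > 0, p_max > 0, p_max < 1)
  intens <- assay(x, "intensity")
  bait <- colData(x)$group == "bait"
  nb <- sum(bait); nc <- sum(!bait)
  if (nb < 2L || nc < 2L) stop("need >= 2 replicates per group")
  floor_val <- NA_real_
  if (impute == "floor") {
    nz <- intens[!is.na(intens) & intens > 0]
    floor_val <- if (length(nz)) floor_factor * min(nz) else 1
    work <- intens
    work[is.na(work) | work < floor_val] <- floor_val
    L <- log2(work)
    mb <- rowMeans(L[, bait, drop = FALSE])
    mc <- rowMeans(L[, !bait, drop = FALSE])
    vb <- apply(L[, bait, drop = FALSE], 1L, var)
    vc <- apply(L[, !bait, drop = FALSE], 1L, var)
    kb <- rep(nb, nrow(x)); kc <- rep(nc, nrow(x))
    fc <- rowMeans(work[, bait, drop = FALSE]) /
      rowMeans(work[, !bait, drop = FALSE])
    untestable <- rep(FALSE, nrow(x))
  } else {
    L <- log2(ifelse(intens == 0, NA, intens))   # zeros unloggable here
    mb <- rowMeans(L[, bait, drop = FALSE], na.rm = TRUE)
    mc <- rowMeans(L[, !bait, drop = FALSE], na.rm = TRUE)
    vb <- apply(L[, bait, drop = FALSE], 1L, var, na.rm = TRUE)
    vc <- apply(L[, !bait, drop = FALSE], 1L, var, na.rm = TRUE)
    kb <- rowSums(!is.na(L[, bait, drop = FALSE]))
    kc <- rowSums(!is.na(L[, !bait, drop = FALSE]))
    fc <- rowMeans(intens[, bait, drop = FALSE], na.rm = TRUE) /
      rowMeans(intens[, !bait, drop = FALSE], na.rm = TRUE)
    untestable <- kb < 2L | kc < 2L
  }
  if (var_equal) {
    sp2 <- ((kb - 1) * vb + (kc - 1) * vc) / (kb + kc - 2)
    se <- sqrt(sp2 * (1 / kb + 1 / kc))
    df <- kb + kc - 2
  } else {
    se <- sqrt(vb / kb + vc / kc)
    df <- (vb / kb + vc / kc)^2 /
      ((vb / kb)^2 / (kb - 1) + (vc / kc)^2 / (kc - 1))
  }
  tstat <- (mb - mc) / se
  p <- 2 * pt(-abs(tstat), df)
  # identical groups (zero pooled variance, zero difference) are null, not NA
  degen <- !is.na(se) & se == 0
  p[degen & (mb - mc) == 0] <- 1
  p[degen & (mb - mc) != 0] <- 0
  p[untestable] <- NA_real_
  fc[untestable] <- NA_real_
  delta <- if ("delta_ibaq" %in% colnames(rowData(x)))
    rowData(x)$delta_ibaq else rep(NA_real_, nrow(x))
  sel <- !is.na(p) & !is.na(fc) & fc >= fc_min & p < p_max
  df_out <- DataFrame(
    protein_id = rowData(x)$protein_id,
    gene_symbol = rowData(x)$gene_symbol,
    n_peptides = rowData(x)$n_peptides,
    mean_bait = unname(mb), mean_control = unname(mc),
    log2fc = unname(log2(fc)), fold_change = unname(fc),
    p_value = unname(p), q_value = unname(p.adjust(p, "BH")),
    delta_ibaq = unname(delta),
    untestable = unname(untestable),
    selected = unname(sel))
  new("EnrichmentResults", df_out,
      thresholds = list(fc_min = fc_min, p_max = p_max, impute = impute,
                        floor_factor = floor_factor, floor = floor_val,
                        var_equal = var_equal))
})

#' Select enriched hits
#'
#' Subset of records with \code{fold_change >= fc_min} and
#' \code{p_value < p_max} (the flags computed by \code{\link{testEnrichment}}),
#' sorted by descending delta-iBAQ when available (rank-plot order).
#'
#' @param res an \linkS4class{EnrichmentResults}.
#' @return the selected rows, same class.
#' @export
selectHits <- function(res) {
  stopifnot(is(res, "EnrichmentResults"))
  out <- res[which(res$selected), ]
  if (any(!is.na(out$delta_ibaq)))
    out <- out[order(-out$delta_ibaq, na.last = TRUE), ]
  out
}

#' Collapse selected proteins to unique genes
#'
#' @param res an \linkS4class{EnrichmentResults} (typically the output of
#'   \code{\link{selectHits}}).
#' @return list with \code{genes} (unique symbols, first spelling kept;
#'   proteins lacking a symbol are kept under their protein id with a
#'   warning) and \code{mapping} (gene to contributing protein ids).
#' @export
collapseToGenes <- function(res) {
  gene <- as.character(res$gene_symbol)
  nogene <- is.na(gene) | !nzchar(gene)
  if (any(nogene)) {
    warning(sum(nogene), " protein(s) without gene symbol kept under ",
            "protein_id")
    gene[nogene] <- as.character(res$protein_id)[nogene]
  }
  key <- normalizeIds(gene)
  genes <- gene[!duplicated(key)]
  mapping <- split(as.character(res$protein_id), key)[normalizeIds(genes)]
  names(mapping) <- genes
  list(genes = genes, mapping = mapping)
}
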