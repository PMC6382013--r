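#' PeptideExperiment: peptide-level label-free intensities
#'
#' A \linkS4class{SummarizedExperiment} subclass holding one peptide per row
#' and one MS run per column.  The single assay \code{"intensity"} stores raw
#' label-free intensities; \code{NA} marks a peptide not observed in a run,
#' which is distinct from a measured zero.  \code{rowData} carries
#' \code{peptide_sequence}, \code{protein_id} and \code{gene_symbol};
#' \code{colData} carries \code{group} (\code{"bait"} or \code{"control"}) and
#' \code{replicate}.
#'
#' @export
setClass("PeptideExperiment", contains = "SummarizedExperiment")

setValidity("PeptideExperiment", function(object) {
  msg <- character()
  if (!"intensity" %in% names(assays(object)))
    msg <- c(msg, "assay 'intensity' is required")
  rd <- rowData(object)
  need <- c("peptide_sequence", "protein_id", "gene_symbol")
  miss <- setdiff(need, colnames(rd))
  if (length(miss))
    msg <- c(msg, paste0("rowData lacks column(s): ",
                         paste(miss, collapse = ", ")))
  cd <- colData(object)
  if (!all(c("group", "replicate") %in% colnames(cd))) {
    msg <- c(msg, "colData needs 'group' and 'replicate'")
  } else if (!all(cd$group %in% c("bait", "control"))) {
    msg <- c(msg, "group must be 'bait' or 'control'")
  }
  if ("intensity" %in% names(assays(object))) {
    x <- assay(object, "intensity")
    if (any(x < 0, na.rm = TRUE))
      msg <- c(msg, "intensities must be non-negative (NA = missing)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PeptideExperiment
#'
#' @param intensity numeric matrix, peptides x samples; \code{NA} = missing
#'   measurement (not zero).
#' @param peptides data.frame with columns \code{peptide_sequence},
#'   \code{protein_id}, \code{gene_symbol} (one row per row of
#'   \code{intensity}).
#' @param samples data.frame with columns \code{group} ("bait"/"control") and
#'   \code{replicate}, rownames matching \code{colnames(intensity)}.
#' @param validate_sequences check that peptide sequences use only the 20
#'   standard amino-acid letters (default \code{TRUE}).
#' @return A \linkS4class{PeptideExperiment}.
#' @export
PeptideExperiment <- function(intensity, peptides, samples,
                              validate_sequences = TRUE) {
  intensity <- as.matrix(intensity)
  storage.mode(intensity) <- "double"
  if (nrow(peptides) != nrow(intensity))
    stop("'peptides' must have one row per row of 'intensity'")
  if (nrow(samples) != ncol(intensity))
    stop("'samples' must have one row per column of 'intensity'")
  if (validate_sequences) {
    bad <- grepl(paste0("[^", .AA20, "]"), peptides$peptide_sequence)
    if (any(bad))
      stop("non-standard residues in peptide sequence(s), e.g. ",
           peptides$peptide_sequence[which(bad)[1L]])
  }
  se <- SummarizedExperiment(
    assays = list(intensity = intensity),
    rowData = DataFrame(peptides),
    colData = DataFrame(samples))
  new("PeptideExperiment", se)
}

#' ProteinQuant: protein-level rolled-up intensities
#'
#' A \linkS4class{SummarizedExperiment} subclass with one protein per row.
#' Assay \code{"intensity"} holds the per-sample sum of the protein's peptide
#' intensities (\code{NA} when every peptide was missing in that sample); an
#' optional assay \code{"ibaq"} holds per-sample iBAQ values.  \code{rowData}
#' carries \code{protein_id}, \code{gene_symbol}, \code{n_peptides} (distinct
#' peptide sequences) and, once \code{\link{addIbaq}} has run,
#' \code{observable_peptides} and \code{delta_ibaq}.
#'
#' @export
setClass("ProteinQuant", contains = "SummarizedExperiment")

setValidity("ProteinQuant", function(object) {
  msg <- character()
  if (!"intensity" %in% names(assays(object)))
    msg <- c(msg, "assay 'intensity' is required")
  rd <- rowData(object)
  need <- c("protein_id", "gene_symbol", "n_peptides")
  miss <- setdiff(need, colnames(rd))
  if (length(miss))
    msg <- c(msg, paste0("rowData lacks column(s): ",
                         paste(miss, collapse = ", ")))
  if ("n_peptides" %in% colnames(rd) && length(rd$n_peptides) &&
      any(rd$n_peptides < 1L))
    msg <- c(msg, "n_peptides must be >= 1")
  if (length(msg)) msg else TRUE
})

#' EnrichmentResults: per-protein bait-vs-control test results
#'
#' A \linkS4class{DataFrame} subclass with one row per protein and columns
#' \code{protein_id}, \code{gene_symbol}, \code{n_peptides},
#' \code{mean_bait}, \code{mean_control} (log2 scale), \code{log2fc},
#' \code{fold_change} (ratio of raw group means), \code{p_value},
#' \code{q_value} (Benjamini-Hochberg), \code{delta_ibaq} (when iBAQ inputs
#' were supplied), \code{untestable} and \code{selected}.  The thresholds used
#' for selection are kept in the \code{thresholds} slot.
#'
#' @export
setClass("EnrichmentResults", contains = "DFrame",
         representation(thresholds = "list"))

#' @describeIn EnrichmentResults compact display with the hit-selection
#'   summary.
#' @param object an \code{EnrichmentResults}.
#' @export
setMethod("show", "EnrichmentResults", function(object) {
  th <- object@thresholds
  cat(sprintf(
    "EnrichmentResults: %d proteins, %d selected (FC >= %g, P < %g)\n",
    nrow(object), sum(object$selected, na.rm = TRUE),
    th$fc_min, th$p_max))
  callNextMethod()
})

#' FrapFit: fitted FRAP recovery model
#'
#' Holds the result of \code{\link{fitRecovery}}: the model type
#' (\code{"single"} or \code{"double"}), the parameter estimates
#' (\code{mobile_fraction}, \code{fast_fraction}, \code{t_half_fast},
#' \code{t_half_slow}, all in fractions/seconds), the residual RMS, a
#' convergence flag, any quality flags (e.g. \code{"super_recovery"} when the
#' mobile fraction exceeds 1) and the normalized curve with fitted values.
#'
#' @export
setClass("FrapFit", representation(
  model = "character",
  estimates = "numeric",
  rmse = "numeric",
  converged = "logical",
  flags = "character",
  curve = "data.frame"))

#' @describeIn FrapFit compact display of the fitted parameters.
#' @param object a \code{FrapFit}.
#' @export
setMethod("show", "FrapFit", function(object) {
  e <- object@estimates
  cat(sprintf("FrapFit (%s exponential)%s\n", object@model,
              if (object@converged) "" else " [NOT CONVERGED]"))
  cat(sprintf("  mobile fraction: %.1f%%\n", 100 * e[["mobile_fraction"]]))
  if (object@model == "double")
    cat(sprintf("  fast pool: %.1f%% (t1/2 = %.1f s)\n",
                100 * e[["fast_fraction"]], e[["t_half_fast"]]))
  cat(sprintf("  slow t1/2: %.1f s\n", e[["t_half_slow"]]))
  cat(sprintf("  residual RMS: %.4g on %d points\n", object@rmse,
              nrow(object@curve)))
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

#' RunReport: end-to-end pipeline run summary
#'
#' Carries the identification funnel (peptides in, proteins, proteins after
#' the single-peptide filter, hits, genes), the per-stage status and outputs,
#' the configuration echo and the RNG seeds used.
#'
#' @export
setClass("RunReport", representation(
  funnel = "integer",
  stages = "list",
  config = "list",
  seeds = "integer",
  version = "character"))

#' @describeIn RunReport display the counts funnel and stage status.
#' @param object a \code{RunReport}.
#' @export
setMethod("show", "RunReport", function(object) {
  f <- object@funnel
  cat("proxitome run report (v", object@version, ")\n", sep = "")
  cat(sprintf("  peptides in:          %d\n", f[["peptides"]]))
  cat(sprintf("  proteins:             %d\n", f[["proteins"]]))
  cat(sprintf("  multi-peptide:        %d\n", f[["proteins_filtered"]]))
  cat(sprintf("  hits:                 %d\n", f[["hits"]]))
  cat(sprintf("  genes:                %d\n", f[["genes"]]))
  st <- vapply(object@stages, function(s) s$status, character(1))
  cat("  stages: ", paste(sprintf("%s[%s]", names(st), st),
                          collapse = " "), "\n")
})
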