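# End-to-end orchestration: rollup -> single-peptide filter -> iBAQ ->
# enrichment test -> hit selection -> gene collapse, with optional
# interactome comparison, tissue-pattern calling and network tier layering.
# Each stage runs under tryCatch: a failure marks the stage and later
# dependent stages are skipped, while completed outputs are kept.

#' Run the analysis pipeline end to end
#'
#' @param peptides a \linkS4class{PeptideExperiment}, or a peptide-table file
#'   path (then \code{metadata} is required).
#' @param metadata sample-metadata path when \code{peptides} is a path.
#' @param sequences optional protein sequences (\code{AAStringSet}, named
#'   character vector, or FASTA path) enabling the iBAQ stage.
#' @param reference_sets optional named list of gene sets to partition
#'   against the hit genes (e.g. a prior interactome and a curated list).
#' @param expression optional list with \code{fpkm} (genes x samples),
#'   \code{tissue} (per-sample labels) and \code{target}, enabling the
#'   tissue-pattern stage and hit-set enrichment fractions.
#' @param edges optional \code{igraph} (or edge-list path) for tier layering.
#' @param seed_protein bait node name for tier layering.
#' @param config named list overriding pipeline thresholds: \code{fc_min}
#'   (10), \code{p_max} (0.001), \code{min_peptides} (2), \code{impute}
#'   ("floor"), \code{floor_factor} (0.5), digest parameters \code{min_len}
#'   (7), \code{max_len} (30), \code{missed_cleavages} (0).
#' @param outdir optional directory; when given, every stage table is
#'   written there as TSV.
#' @return a \linkS4class{RunReport}; stage outputs are in
#'   \code{report@stages[[name]]$result}.
#' @export
runPipeline <- function(peptides, metadata = NULL, sequences = NULL,
                        reference_sets = NULL, expression = NULL,
                        edges = NULL, seed_protein = NULL,
                        config = list(), outdir = NULL) {
  cfg <- utils::modifyList(list(
    fc_min = 10, p_max = 0.001, min_peptides = 2L,
    impute = "floor", floor_factor = 0.5,
    min_len = 7L, max_len = 30L, missed_cleavages = 0L), config)
  stages <- list()
  run_stage <- function(name, fun) {
    res <- tryCatch(list(status = "ok", result = fun()),
                    error = function(e)
                      list(status = "failed", error = conditionMessage(e)))
    stages[[name]] <<- res
    if (res$status == "failed")
      warning("stage '", name, "' failed: ", res$error, call. = FALSE)
    res
  }
  if (is.character(peptides)) {
    if (is.null(metadata))
      stop("metadata path required when peptides is a file path")
    peptides <- readPeptideTable(peptides, metadata)
  }
  if (is.character(sequences) && length(sequences) == 1L &&
      file.exists(sequences))
    sequences <- Biostrings::readAAStringSet(sequences)

  st <- run_stage("rollup", function() rollupPeptides(peptides))
  pq <- if (st$status == "ok") st$result else NULL
  pq_f <- NULL
  if (!is.null(pq)) {
    st <- run_stage("filter", function()
      filterSinglePeptide(pq, cfg$min_peptides))
    pq_f <- if (st$status == "ok") st$result else NULL
  }
  if (!is.null(pq_f) && !is.null(sequences)) {
    st <- run_stage("ibaq", function()
      addIbaq(pq_f, sequences, min_len = cfg$min_len,
              max_len = cfg$max_len,
              missed_cleavages = cfg$missed_cleavages))
    if (st$status == "ok") pq_f <- st$result
  }
  res <- hits <- genes <- NULL
  if (!is.null(pq_f)) {
    st <- run_stage("test", function()
      testEnrichment(pq_f, fc_min = cfg$fc_min, p_max = cfg$p_max,
                     impute = cfg$impute,
                     floor_factor = cfg$floor_factor))
    res <- if (st$status == "ok") st$result else NULL
  }
  if (!is.null(res)) {
    st <- run_stage("hits", function() selectHits(res))
    hits <- if (st$status == "ok") st$result else NULL
  }
  if (!is.null(hits)) {
    st <- run_stage("genes", function() collapseToGenes(hits))
    genes <- if (st$status == "ok") st$result else NULL
  }
  if (!is.null(genes) && !is.null(reference_sets)) {
    run_stage("compare", function()
      partitionSets(c(list(hits = genes$genes), reference_sets)))
  }
  if (!is.null(expression)) {
    st <- run_stage("patterns", function()
      callEnrichedGenes(expression$fpkm, expression$tissue,
                        expression$target))
    if (st$status == "ok" && !is.null(genes) &&
        length(st$result$enriched))
      run_stage("fractions", function()
        enrichmentFraction(genes$genes, st$result$enriched))
  }
  if (!is.null(edges) && !is.null(seed_protein)) {
    if (is.character(edges)) edges <- readEdgeList(edges)
    run_stage("tiers", function()
      assignTiers(edges, seed_protein,
                  members = if (!is.null(genes)) genes$genes))
  }
  funnel <- c(
    peptides = nrow(peptides),
    proteins = if (!is.null(pq)) nrow(pq) else NA_integer_,
    proteins_filtered = if (!is.null(pq_f)) nrow(pq_f) else NA_integer_,
    hits = if (!is.null(hits)) nrow(hits) else NA_integer_,
    genes = if (!is.null(genes)) length(genes$genes) else NA_integer_)
  if (!is.null(outdir)) .write_outputs(stages, outdir)
  funnel <- setNames(as.integer(funnel),
                     c("peptides", "proteins", "proteins_filtered",
                       "hits", "genes"))
  new("RunReport", funnel = funnel, stages = stages,
      config = cfg, seeds = integer(0),
      version = as.character(utils::packageVersion("proxitome")))
}

.write_outputs <- function(stages, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(d, f) write.table(
    as.data.frame(d), file.path(outdir, f), sep = "\t", quote = FALSE,
    row.names = FALSE, na = "")
  if (!is.null(stages$test) && stages$test$status == "ok")
    tsv(stages$test$result, "enrichment.tsv")
  if (!is.null(stages$hits) && stages$hits$status == "ok")
    tsv(stages$hits$result, "hits.tsv")
  if (!is.null(stages$genes) && stages$genes$status == "ok")
    writeLines(stages$genes$result$genes, file.path(outdir, "genes.txt"))
  if (!is.null(stages$patterns) && stages$patterns$status == "ok")
    tsv(stages$patterns$result$calls, "pattern_calls.tsv")
  if (!is.null(stages$tiers) && stages$tiers$status == "ok")
    tsv(stages$tiers$result, "tiers.tsv")
  invisible(NULL)
}

#' Funnel counts of a pipeline run
#'
#' @param report a \linkS4class{RunReport}.
#' @return named integer vector: peptides, proteins, proteins_filtered,
#'   hits, genes.
#' @export
funnelCounts <- function(report) {
  stopifnot(is(report, "RunReport"))
  setNames(report@funnel,
           c("peptides", "proteins", "proteins_filtered", "hits", "genes"))
}
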