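# Tissue/cell-type enrichment pattern calling from FPKM profiles.  Three
# pattern rules, evaluated in precedence order (most to least specific):
#   exclusive  — expressed (>= floor) in the target tissue only;
#   multi_high — 2-4 "high" tissues including the target, where high =
#                within fc_threshold-fold of the per-gene maximum, the sum of
#                FPKM exceeds the number of tissues, and every high tissue is
#                >= fc_threshold times every non-high tissue;
#   gradient   — the target holds the single maximum and max/min >= 4.

#' Classify one gene's expression pattern
#'
#' @param expr named FPKM vector, one value per tissue.
#' @param target target tissue label (must be present).
#' @param fc_threshold fold-change threshold defining "high" (default 2).
#' @param floor FPKM floor below which a tissue counts as unexpressed
#'   (default 1).
#' @return list with \code{pattern} (one of \code{"exclusive"},
#'   \code{"multi_high"}, \code{"gradient"}, \code{"none"}) and supporting
#'   statistics (\code{max_tissue}, \code{n_high}, \code{sum_fpkm},
#'   \code{max_min_ratio}).
#' @export
classifyPattern <- function(expr, target, fc_threshold = 2, floor = 1) {
  if (is.null(names(expr))) stop("expr must be named by tissue")
  if (!target %in% names(expr)) stop("target tissue absent from expr")
  if (fc_threshold < 1) stop("fc_threshold must be >= 1")
  x <- as.numeric(expr)
  names(x) <- names(expr)
  n <- length(x)
  mx <- max(x)
  stats <- list(max_tissue = names(x)[which.max(x)],
                n_high = NA_integer_,
                sum_fpkm = sum(x),
                max_min_ratio = if (min(x) > 0) mx / min(x) else Inf)
  pattern <- "none"
  high <- x >= mx / fc_threshold & x >= floor
  stats$n_high <- sum(high)
  if (mx >= floor) {
    other <- setdiff(names(x), target)
    if (x[target] >= floor && all(x[other] < floor)) {
      pattern <- "exclusive"
    } else if (high[[target]] && sum(high) >= 2L && sum(high) <= 4L &&
               sum(x) > n &&
               (all(high) || min(x[high]) >= fc_threshold * max(x[!high]))) {
      pattern <- "multi_high"
    } else if (x[[target]] == mx && sum(x == mx) == 1L &&
               min(x) > 0 && mx / min(x) >= 4) {
      pattern <- "gradient"
    }
  }
  c(list(pattern = pattern), stats)
}

#' Call tissue-enriched genes from an FPKM matrix
#'
#' Replicate samples of a tissue are averaged before classification, then
#' \code{\link{classifyPattern}} is applied per gene.  Deterministic and
#' invariant to sample column order.
#'
#' @param fpkm genes x samples matrix.
#' @param tissue character vector mapping each sample (column) to its tissue.
#' @param target target tissue label.
#' @param fc_threshold,floor see \code{\link{classifyPattern}}.
#' @return list with \code{enriched} (genes with a pattern other than
#'   \code{"none"}) and \code{calls} (\code{DataFrame}: gene, pattern,
#'   supporting statistics).
#' @export
callEnrichedGenes <- function(fpkm, tissue, target, fc_threshold = 2,
                              floor = 1) {
  if (length(tissue) != ncol(fpkm))
    stop("one tissue label per sample column required")
  if (!target %in% tissue) stop("target tissue absent from labels")
  if (nrow(fpkm) == 0L)
    return(list(enriched = character(0),
                calls = DataFrame(gene = character(0),
                                  pattern = character(0))))
  tiss <- unique(tissue)
  avg <- vapply(tiss, function(tt)
    rowMeans(fpkm[, tissue == tt, drop = FALSE]), numeric(nrow(fpkm)))
  avg <- matrix(avg, nrow = nrow(fpkm),
                dimnames = list(rownames(fpkm), tiss))
  calls <- lapply(seq_len(nrow(avg)), function(i)
    classifyPattern(avg[i, ], target, fc_threshold, floor))
  calls <- DataFrame(
    gene = rownames(fpkm),
    pattern = vapply(calls, `[[`, character(1), "pattern"),
    max_tissue = vapply(calls, `[[`, character(1), "max_tissue"),
    n_high = vapply(calls, `[[`, integer(1), "n_high"),
    sum_fpkm = vapply(calls, `[[`, numeric(1), "sum_fpkm"),
    max_min_ratio = vapply(calls, `[[`, numeric(1), "max_min_ratio"))
  list(enriched = calls$gene[calls$pattern != "none"], calls = calls)
}

#' Printed-style enrichment fractions
#'
#' Reports what share of an interactome subset is tissue-enriched and what
#' share of the enriched-gene pool the overlap represents, as percentages
#' rounded to the requested precision (default one decimal, the usual
#' printed precision).
#'
#' Either pass two character vectors (\code{subset}, \code{enriched}) or the
#' three counts directly (\code{overlap}, \code{subset_size},
#' \code{enriched_size}).
#'
#' @param subset interactome subset (character vector), or the overlap count
#'   when used in count mode.
#' @param enriched enriched gene set (character vector), or the subset size
#'   in count mode.
#' @param enriched_size total enriched-pool size (count mode only).
#' @param digits rounding digits for the percentages (default 1).
#' @return named numeric vector:
#'   \code{pct_of_subset} = 100 * overlap / subset size,
#'   \code{pct_of_enriched} = 100 * overlap / enriched total.
#' @export
enrichmentFraction <- function(subset, enriched, enriched_size = NULL,
                               digits = 1) {
  if (is.character(subset) && is.character(enriched)) {
    overlap <- sum(normalizeIds(unique(subset)) %in%
                   normalizeIds(unique(enriched)))
    n_sub <- length(unique(normalizeIds(subset)))
    n_enr <- if (is.null(enriched_size))
      length(unique(normalizeIds(enriched))) else enriched_size
  } else {
    overlap <- as.numeric(subset)
    n_sub <- as.numeric(enriched)
    n_enr <- as.numeric(enriched_size)
  }
  if (is.null(n_enr) || n_sub == 0 || n_enr == 0)
    stop("zero or missing denominator")
  c(pct_of_subset = round(100 * overlap / n_sub, digits),
    pct_of_enriched = round(100 * overlap / n_enr, digits))
}
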