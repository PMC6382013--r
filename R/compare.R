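# Interactome set comparison: Venn-style partitioning, functional-category
# distributions by count or abundance, and Fisher overrepresentation tests.

#' Partition named sets into disjoint Venn regions
#'
#' Every element of the union is assigned to exactly one region labeled by
#' the subset of input sets it belongs to (names joined with \code{"&"}).
#' Membership is case-insensitive (see \code{\link{normalizeIds}}); the first
#' spelling seen is reported.
#'
#' @param sets named list of two or more character vectors.
#' @return list with \code{regions} (region label to member vector, all
#'   \code{2^k - 1} signatures present, possibly empty) and \code{sizes}
#'   (named integer vector).
#' @export
partitionSets <- function(sets) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be named")
  if (length(sets) < 2L) stop("need at least 2 sets")
  keys <- lapply(sets, normalizeIds)
  uni_keys <- unique(unlist(keys, use.names = FALSE))
  uni_orig <- unlist(sets, use.names = FALSE)
  uni_orig <- uni_orig[!duplicated(normalizeIds(uni_orig))]
  names(uni_orig) <- normalizeIds(uni_orig)
  member <- vapply(keys, function(k) uni_keys %in% k,
                   logical(length(uni_keys)))
  member <- matrix(member, nrow = length(uni_keys),
                   dimnames = list(uni_keys, names(sets)))
  nm_sorted <- sort(names(sets))           # canonical region labels
  sig <- apply(member, 1L, function(m)
    paste(nm_sorted[nm_sorted %in% names(sets)[m]], collapse = "&"))
  # all non-empty subset signatures, in canonical order
  k <- length(sets)
  all_sigs <- unlist(lapply(seq_len(k), function(sz)
    utils::combn(nm_sorted, sz, paste, collapse = "&", simplify = FALSE)))
  regions <- setNames(lapply(all_sigs, function(s)
    unname(uni_orig[uni_keys[sig == s]])), all_sigs)
  list(regions = regions, sizes = vapply(regions, length, integer(1)))
}

#' Functional-category distribution of a gene set
#'
#' Distributes the members over a one-category-per-gene vocabulary, by count
#' or weighted by abundance (e.g. delta-iBAQ, negative weights clipped to
#' zero).  Members absent from the annotation form an explicit
#' \code{"unannotated"} category.
#'
#' @param annotation named character vector, gene to category.
#' @param members character vector of genes.
#' @param weights optional named numeric vector (gene to abundance) switching
#'   to abundance mode; an all-zero total is an error.
#' @return named numeric vector of fractions summing to 1.
#' @export
categoryDistribution <- function(annotation, members, weights = NULL) {
  if (length(members) == 0L) stop("empty member set")
  ann <- setNames(as.character(annotation), normalizeIds(names(annotation)))
  key <- normalizeIds(members)
  cat_of <- ann[key]
  cat_of[is.na(cat_of)] <- "unannotated"
  if (is.null(weights)) {
    w <- rep(1, length(members))
  } else {
    w <- setNames(as.numeric(weights), normalizeIds(names(weights)))[key]
    w[is.na(w)] <- 0
    w <- pmax(w, 0)
    if (sum(w) == 0) stop("all-zero weights in abundance mode")
  }
  tot <- tapply(w, cat_of, sum)
  out <- as.numeric(tot) / sum(w)
  setNames(out, names(tot))
}

#' Overrepresentation P-value and odds ratio from 2x2 counts
#'
#' Vectorized core of \code{\link{fisherOverrep}}: \code{a} = members that
#' are enriched, \code{b} = members only, \code{c} = enriched only,
#' \code{d} = neither.  The one-sided \code{"greater"} P-value is the
#' hypergeometric tail \eqn{P(X \ge a)}; \code{"two.sided"} defers to
#' \code{stats::fisher.test} (not vectorized).
#'
#' @param a,b,c,d non-negative integer counts (recycled).
#' @param alternative \code{"greater"} (default) or \code{"two.sided"}.
#' @return list with \code{p_value} and \code{odds_ratio} (sample
#'   \code{ad/bc}, \code{Inf} when \code{bc = 0} and \code{ad > 0},
#'   \code{NaN} for the empty table).
#' @export
fisherFromCounts <- function(a, b, c, d,
                             alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (any(c(a, b, c, d) < 0)) stop("counts must be non-negative")
  if (alternative == "greater") {
    p <- phyper(a - 1L, a + c, b + d, a + b, lower.tail = FALSE)
  } else {
    p <- mapply(function(a, b, c, d)
      fisher.test(matrix(c(a, b, c, d), 2L, byrow = TRUE))$p.value,
      a, b, c, d)
  }
  or <- ifelse(b * c == 0, ifelse(a * d > 0, Inf, NaN), (a * d) / (b * c))
  list(p_value = p, odds_ratio = or)
}

#' Fisher's exact overrepresentation test
#'
#' Tests whether \code{members} are overrepresented among \code{enriched}
#' within \code{universe}, on the 2x2 table (a = members and enriched,
#' b = members only, c = enriched only, d = neither).  The default
#' one-sided \code{"greater"} P-value is the hypergeometric tail
#' \eqn{P(X \ge a)}; the odds ratio is the sample \code{ad/bc}
#' (\code{Inf} when \code{bc = 0} and \code{ad > 0}).
#'
#' @param members,enriched,universe character vectors; both sets must be
#'   subsets of the universe.
#' @param alternative \code{"greater"} (default) or \code{"two.sided"}.
#' @return list with \code{table} (2x2 matrix), \code{odds_ratio},
#'   \code{p_value}, \code{alternative}.
#' @export
fisherOverrep <- function(members, enriched, universe,
                          alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  uni <- unique(normalizeIds(universe))
  if (length(uni) == 0L) stop("empty universe")
  mem <- unique(normalizeIds(members))
  enr <- unique(normalizeIds(enriched))
  if (!all(mem %in% uni) || !all(enr %in% uni))
    stop("members and enriched must be subsets of the universe")
  a <- sum(mem %in% enr)
  b <- length(mem) - a
  cc <- length(enr) - a
  d <- length(uni) - a - b - cc
  tab <- matrix(c(a, b, cc, d), 2L, 2L, byrow = TRUE,
                dimnames = list(c("in_set", "not_in_set"),
                                c("enriched", "not_enriched")))
  core <- fisherFromCounts(a, b, cc, d, alternative)
  list(table = tab, odds_ratio = core$odds_ratio,
       p_value = core$p_value, alternative = alternative)
}
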