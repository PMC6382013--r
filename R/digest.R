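# In-silico tryptic digestion and iBAQ (intensity-based absolute
# quantification): a protein's summed intensity divided by its count of
# theoretically observable tryptic peptides.

#' In-silico tryptic digest of a protein sequence
#'
#' Cleaves C-terminal to K or R, by default not when the next residue is
#' proline, and returns the fully tryptic peptides (up to
#' \code{missed_cleavages} missed sites) whose length lies in
#' \code{[min_len, max_len]}.
#'
#' @param sequence amino-acid string (20 standard residues).
#' @param min_len,max_len observable length window (defaults 7 and 30; the
#'   lower bound matches a typical search-engine minimum).
#' @param missed_cleavages maximum missed cleavage sites (default 0, the
#'   usual iBAQ divisor convention).
#' @param exclude_before_proline suppress cleavage before P (default
#'   \code{TRUE}, standard trypsin specificity).
#' @return character vector of observable peptides (possibly empty).
#' @export
digestSequence <- function(sequence, min_len = 7L, max_len = 30L,
                           missed_cleavages = 0L,
                           exclude_before_proline = TRUE) {
  if (length(sequence) != 1L || is.na(sequence) || !nzchar(sequence))
    stop("sequence must be a single non-empty string")
  sequence <- toupper(sequence)
  if (grepl(paste0("[^", .AA20, "]"), sequence))
    stop("non-standard residue in sequence")
  if (min_len < 1L || min_len > max_len)
    stop("need 1 <= min_len <= max_len")
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  cut <- which(aa %in% c("K", "R"))
  cut <- cut[cut < n]
  if (exclude_before_proline) cut <- cut[aa[cut + 1L] != "P"]
  bounds <- c(0L, cut, n)                       # fragment i = (b[i], b[i+1]]
  nfrag <- length(bounds) - 1L
  peps <- character(0)
  for (m in 0:min(missed_cleavages, nfrag - 1L)) {
    from <- bounds[seq_len(nfrag - m)] + 1L
    to <- bounds[seq_len(nfrag - m) + 1L + m]
    len <- to - from + 1L
    ok <- len >= min_len & len <= max_len
    if (any(ok))
      peps <- c(peps, substring(sequence, from[ok], to[ok]))
  }
  peps
}

#' Count theoretically observable tryptic peptides
#'
#' @inheritParams digestSequence
#' @return non-negative integer.
#' @export
countObservablePeptides <- function(sequence, min_len = 7L, max_len = 30L,
                                    missed_cleavages = 0L,
                                    exclude_before_proline = TRUE) {
  length(digestSequence(sequence, min_len, max_len, missed_cleavages,
                        exclude_before_proline))
}

#' iBAQ: intensity per theoretically observable peptide
#'
#' @param protein_intensity non-negative intensity (vectorized).
#' @param observable_count count of observable tryptic peptides (vectorized;
#'   a count of zero yields \code{NA} with a warning — the protein is
#'   flagged, not silently dropped).
#' @return \code{protein_intensity / observable_count}.
#' @export
computeIbaq <- function(protein_intensity, observable_count) {
  if (any(protein_intensity < 0, na.rm = TRUE))
    stop("protein_intensity must be non-negative")
  bad <- !is.na(observable_count) & observable_count == 0
  if (any(bad))
    warning(sum(bad), " protein(s) with zero observable peptides: ",
            "iBAQ undefined (NA)")
  out <- protein_intensity / observable_count
  out[bad] <- NA_real_
  out
}

#' Bait-minus-control iBAQ difference
#'
#' The per-group average iBAQ is taken over the observed (non-missing)
#' replicates; the result is \code{mean(bait) - mean(control)} and may be
#' negative.  An all-missing group yields \code{NA} with a warning.
#'
#' @param bait_ibaq,control_ibaq per-replicate iBAQ values.
#' @return a single delta-iBAQ value.
#' @export
deltaIbaq <- function(bait_ibaq, control_ibaq) {
  if (length(bait_ibaq) == 0L || length(control_ibaq) == 0L)
    stop("both groups must be non-empty")
  if (all(is.na(bait_ibaq)) || all(is.na(control_ibaq))) {
    warning("all-missing group: delta-iBAQ undefined")
    return(NA_real_)
  }
  mean(bait_ibaq, na.rm = TRUE) - mean(control_ibaq, na.rm = TRUE)
}

#' Attach iBAQ values to a protein quantification table
#'
#' Computes per-sample iBAQ (intensity / observable peptide count from an
#' in-silico digest of the supplied sequences) and the per-protein delta-iBAQ
#' (bait average minus control average over observed replicates).  Proteins
#' without a sequence, or whose digest yields no observable peptide, get
#' \code{NA} iBAQ and are flagged in \code{rowData(x)$ibaq_flag}.
#'
#' @param x a \linkS4class{ProteinQuant}.
#' @param sequences an \code{AAStringSet} (or named character vector) of
#'   protein sequences, names matching \code{protein_id}.
#' @param min_len,max_len,missed_cleavages,exclude_before_proline digest
#'   parameters, see \code{\link{digestSequence}}.
#' @return \code{x} with an \code{"ibaq"} assay and rowData columns
#'   \code{observable_peptides}, \code{delta_ibaq}, \code{ibaq_flag}.
#' @export
addIbaq <- function(x, sequences, min_len = 7L, max_len = 30L,
                    missed_cleavages = 0L, exclude_before_proline = TRUE) {
  stopifnot(is(x, "ProteinQuant"))
  seqs <- setNames(as.character(sequences), names(sequences))
  ids <- rowData(x)$protein_id
  counts <- rep(NA_integer_, length(ids))
  hit <- ids %in% names(seqs)
  counts[hit] <- vapply(seqs[ids[hit]], function(s)
    countObservablePeptides(s, min_len, max_len, missed_cleavages,
                            exclude_before_proline), integer(1))
  flag <- ifelse(!hit, "no_sequence",
                 ifelse(!is.na(counts) & counts == 0L,
                        "no_observable_peptide", ""))
  intens <- assay(x, "intensity")
  ok <- !is.na(counts) & counts > 0L
  ibaq <- matrix(NA_real_, nrow(x), ncol(x), dimnames = dimnames(intens))
  ibaq[ok, ] <- intens[ok, , drop = FALSE] / counts[ok]
  bait <- colData(x)$group == "bait"
  delta <- vapply(seq_len(nrow(x)), function(i) {
    if (!ok[i]) return(NA_real_)
    b <- ibaq[i, bait]; cc <- ibaq[i, !bait]
    if (all(is.na(b)) || all(is.na(cc))) return(NA_real_)
    mean(b, na.rm = TRUE) - mean(cc, na.rm = TRUE)
  }, numeric(1))
  assays(x)$ibaq <- ibaq
  rowData(x)$observable_peptides <- counts
  rowData(x)$delta_ibaq <- delta
  rowData(x)$ibaq_flag <- flag
  x
}
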