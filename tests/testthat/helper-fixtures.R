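# Small in-code fixtures shared across test files.

# Three peptides over two proteins, 2 bait + 2 control samples, with one
# missing cell and one bait-only peptide.
tinyPeptideExperiment <- function() {
  x <- matrix(c(100, 200, 150, 250,
                200, NA,  300, 400,
                500, 600, NA,  NA),
              nrow = 3, byrow = TRUE,
              dimnames = list(NULL, c("b1", "b2", "c1", "c2")))
  peptides <- data.frame(
    peptide_sequence = c("AAAAAAAK", "CCCCCCCR", "DDDDDDDK"),
    protein_id = c("P1", "P1", "P2"),
    gene_symbol = c("GENEA", "GENEA", "GENEB"))
  samples <- data.frame(group = c("bait", "bait", "control", "control"),
                        replicate = c(1L, 2L, 1L, 2L),
                        row.names = c("b1", "b2", "c1", "c2"))
  PeptideExperiment(x, peptides, samples)
}

# ProteinQuant built directly from per-protein log2 group values
# (one peptide pattern row per protein, 6v6 layout by default).
quantFromLog2 <- function(bait_log2, control_log2, n_peptides = NULL) {
  bait_log2 <- as.matrix(bait_log2)
  control_log2 <- as.matrix(control_log2)
  m <- cbind(2^bait_log2, 2^control_log2)
  nb <- ncol(bait_log2); nc <- ncol(control_log2)
  colnames(m) <- c(sprintf("b%d", seq_len(nb)), sprintf("c%d", seq_len(nc)))
  n <- nrow(m)
  if (is.null(n_peptides)) n_peptides <- rep(2L, n)
  se <- SummarizedExperiment(
    assays = list(intensity = m),
    rowData = S4Vectors::DataFrame(
      protein_id = sprintf("P%03d", seq_len(n)),
      gene_symbol = sprintf("G%03d", seq_len(n)),
      n_peptides = n_peptides),
    colData = S4Vectors::DataFrame(
      group = rep(c("bait", "control"), c(nb, nc)),
      replicate = c(seq_len(nb), seq_len(nc)),
      row.names = colnames(m)))
  new("ProteinQuant", se)
}

# Closed-form pooled-variance two-sided t-test (independent oracle).
pooledT <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, df = na + nb - 2, p = 2 * pt(-abs(t), na + nb - 2))
}
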