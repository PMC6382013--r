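test_that("peptide rollup sums per sample and propagates missingness", {
  pq <- rollupPeptides(tinyPeptideExperiment())
  expect_s4_class(pq, "ProteinQuant")
  x <- assay(pq, "intensity")
  expect_equal(x["P1", "b1"], 300)          # 100 + 200, sum oracle
  expect_equal(x["P1", "b2"], 200)          # NA contributes nothing
  expect_true(all(is.na(x["P2", c("c1", "c2")])))  # all-missing stays NA
  expect_equal(rowData(pq)$n_peptides, c(2L, 1L))
  expect_equal(rowData(pq)$gene_symbol, c("GENEA", "GENEB"))
})

test_that("unassigned peptides are reported, not dropped silently", {
  pe <- tinyPeptideExperiment()
  rowData(pe)$protein_id[2] <- ""
  expect_warning(pq <- rollupPeptides(pe), "unassigned")
  expect_equal(nrow(pq), 2L)
  expect_equal(nrow(metadata(pq)$unassigned), 1L)
})

test_that("single-peptide exclusion counts sequences, not observations", {
  pq <- rollupPeptides(tinyPeptideExperiment())
  kept <- filterSinglePeptide(pq)
  expect_equal(rowData(kept)$protein_id, "P1")   # P2 has one peptide
  # two distinct sequences observed in a single sample still count as two
  x <- matrix(c(10, NA, NA, NA,
                20, NA, NA, NA), 2, 4, byrow = TRUE,
              dimnames = list(NULL, c("b1", "b2", "c1", "c2")))
  pe <- PeptideExperiment(
    x,
    data.frame(peptide_sequence = c("AAAAAAAK", "CCCCCCCR"),
               protein_id = "P9", gene_symbol = "G9"),
    data.frame(group = c("bait", "bait", "control", "control"),
               replicate = c(1, 2, 1, 2),
               row.names = colnames(x)))
  expect_equal(nrow(filterSinglePeptide(rollupPeptides(pe))), 1L)
})

test_that("t statistics match the closed-form pooled-variance oracle", {
  res <- testEnrichment(quantFromLog2(rbind(c(9, 10, 11)),
                                      rbind(c(5, 6, 7))))
  oracle <- pooledT(c(9, 10, 11), c(5, 6, 7))
  expect_equal(oracle$t, 4.899, tolerance = 1e-3)
  expect_equal(res$p_value, oracle$p, tolerance = 1e-10)
  expect_equal(res$p_value, 0.00805, tolerance = 1e-3)
  expect_equal(res$mean_bait - res$mean_control, 4)
  # identical groups: null by symmetry
  res0 <- testEnrichment(quantFromLog2(rbind(c(9, 10, 11)),
                                       rbind(c(9, 10, 11))))
  expect_equal(res0$p_value, 1)
  expect_equal(res0$log2fc, 0)
  expect_equal(res0$fold_change, 1)
})

test_that("vectorized test equals stats::t.test per protein", {
  set.seed(21)
  b <- matrix(rnorm(20 * 6, 20, 1), 20)
  c_ <- matrix(rnorm(20 * 6, 19, 1.5), 20)
  res <- testEnrichment(quantFromLog2(b, c_))
  for (i in seq_len(20)) {
    tt <- t.test(b[i, ], c_[i, ], var.equal = TRUE)
    expect_equal(res$p_value[i], tt$p.value, tolerance = 1e-12)
  }
  resw <- testEnrichment(quantFromLog2(b, c_), var_equal = FALSE)
  for (i in c(1, 7, 13)) {
    tt <- t.test(b[i, ], c_[i, ], var.equal = FALSE)
    expect_equal(resw$p_value[i], tt$p.value, tolerance = 1e-12)
  }
})

test_that("fold change is the ratio of raw means and 2^log2fc", {
  b <- rbind(c(10, 10.5, 11), c(20, 20, 20))
  c_ <- rbind(c(5, 5.5, 6), c(19, 19, 19))
  res <- testEnrichment(quantFromLog2(b, c_))
  expect_equal(res$fold_change,
               rowMeans(2^b) / rowMeans(2^c_), tolerance = 1e-12)
  expect_equal(res$fold_change, 2^res$log2fc, tolerance = 1e-9)
})

test_that("hit selection applies both thresholds with inclusive FC", {
  mk <- function(fc, p) {
    # build a record table directly through the class for threshold logic
    df <- S4Vectors::DataFrame(protein_id = "P", gene_symbol = "G",
                               n_peptides = 2L, mean_bait = 1,
                               mean_control = 0, log2fc = log2(fc),
                               fold_change = fc, p_value = p, q_value = p,
                               delta_ibaq = NA_real_, untestable = FALSE,
                               selected = fc >= 10 & p < 0.001)
    new("EnrichmentResults", df,
        thresholds = list(fc_min = 10, p_max = 0.001))
  }
  expect_equal(nrow(selectHits(mk(12, 5e-4))), 1L)
  expect_equal(nrow(selectHits(mk(12, 0.5))), 0L)
  expect_equal(nrow(selectHits(mk(9.99, 1e-6))), 0L)
  expect_equal(nrow(selectHits(mk(10, 5e-4))), 1L)     # inclusive boundary
})

test_that("tightening thresholds never adds hits", {
  sim <- simulateBioid(n_proteins = 120, n_true = 20, seed = 31)
  pq <- filterSinglePeptide(rollupPeptides(sim$peptides))
  base <- selectHits(testEnrichment(pq, fc_min = 5, p_max = 0.01))
  for (fc in c(10, 20)) for (pm in c(0.001, 1e-4)) {
    tighter <- selectHits(testEnrichment(pq, fc_min = fc, p_max = pm))
    expect_true(all(tighter$protein_id %in% base$protein_id))
  }
})

test_that("floor imputation keeps bait-only proteins testable", {
  x <- matrix(c(2^20, 2^20.5, 2^20.2, NA, NA, NA), 1,
              dimnames = list(NULL, c("b1", "b2", "b3", "c1", "c2", "c3")))
  se <- SummarizedExperiment(
    assays = list(intensity = x),
    rowData = S4Vectors::DataFrame(protein_id = "P1", gene_symbol = "G1",
                                   n_peptides = 3L),
    colData = S4Vectors::DataFrame(
      group = rep(c("bait", "control"), each = 3),
      replicate = rep(1:3, 2), row.names = colnames(x)))
  res <- testEnrichment(new("ProteinQuant", se))
  expect_false(res$untestable)
  expect_true(is.finite(res$fold_change) && res$fold_change > 1)
  rese <- testEnrichment(new("ProteinQuant", se), impute = "exclude")
  expect_true(rese$untestable)
  expect_true(is.na(rese$p_value))
})

test_that("gene collapse dedupes isoforms and keeps the mapping", {
  df <- S4Vectors::DataFrame(
    protein_id = c("P1", "P2", "P3"),
    gene_symbol = c("VCL", "vcl", "JUP"),
    n_peptides = 2L, mean_bait = 1, mean_control = 0, log2fc = 1,
    fold_change = 2, p_value = 0.5, q_value = 0.5, delta_ibaq = NA_real_,
    untestable = FALSE, selected = TRUE)
  res <- new("EnrichmentResults", df, thresholds = list(fc_min = 10,
                                                        p_max = 0.001))
  g <- collapseToGenes(res)
  expect_equal(g$genes, c("VCL", "JUP"))
  expect_equal(g$mapping$VCL, c("P1", "P2"))
  empty <- collapseToGenes(res[0, ])
  expect_length(empty$genes, 0)
  df$gene_symbol[3] <- ""
  res2 <- new("EnrichmentResults", df, thresholds = list())
  expect_warning(g2 <- collapseToGenes(res2), "without gene symbol")
  expect_true("P3" %in% g2$genes)
})
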