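test_that("peptide tables read with missing-vs-zero distinction", {
  tab <- data.frame(
    peptide_sequence = c("AAAAAAAK", "CCCCCCCR", "DDDDDDDK"),
    protein_id = c("P1", "P1", "P2"),
    gene_symbol = c("GA", "GA", "GB"))
  samp <- paste0(rep(c("b", "c"), each = 6), 1:6)
  intens <- matrix(round(runif(36, 100, 1000)), 3, 12,
                   dimnames = list(NULL, samp))
  tab <- cbind(tab, intens)
  tab[2, "b3"] <- NA                       # empty cell on write
  tab[3, "c1"] <- 0                        # measured zero stays zero
  f <- tempfile(); fm <- tempfile()
  write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  write.table(data.frame(sample_id = samp,
                         group = rep(c("bait", "control"), each = 6),
                         replicate = rep(1:6, 2)),
              fm, sep = "\t", quote = FALSE, row.names = FALSE)
  pe <- readPeptideTable(f, fm)
  expect_s4_class(pe, "PeptideExperiment")
  expect_equal(dim(pe), c(3L, 12L))
  expect_true(is.na(assay(pe, "intensity")[2, "b3"]))
  expect_true(assay(pe, "intensity")[3, "c1"] == 0)
  expect_equal(colData(pe)$group, rep(c("bait", "control"), each = 6))
})

test_that("peptide table validation rejects bad input", {
  f <- tempfile(); fm <- tempfile()
  writeLines(c("peptide_sequence\tprotein_id\tgene_symbol\ts1\ts2\ts3\ts4",
               "AAAAAAAK\tP1\tG1\t-5\t1\t1\t1"), f)
  writeLines(c("sample_id\tgroup\treplicate", "s1\tbait\t1", "s2\tbait\t2",
               "s3\tcontrol\t1", "s4\tcontrol\t2"), fm)
  expect_error(readPeptideTable(f, fm), "negative")
  writeLines(c("peptide_sequence\tprotein_id\tgene_symbol\ts1\tsX\ts3\ts4",
               "AAAAAAAK\tP1\tG1\t5\t1\t1\t1"), f)
  expect_error(readPeptideTable(f, fm), "absent")
  writeLines("peptide_sequence\tprotein_id\tgene_symbol\ts1\ts2\ts3\ts4", f)
  expect_error(readPeptideTable(f, fm), "empty")
  expect_error(PeptideExperiment(
    matrix(1, 1, 2, dimnames = list(NULL, c("a", "b"))),
    data.frame(peptide_sequence = "AAAX1AAK", protein_id = "P",
               gene_symbol = "G"),
    data.frame(group = c("bait", "control"), replicate = c(1, 1),
               row.names = c("a", "b"))),
    "residue")
})

test_that("peptide table write/read round-trips bit-identically", {
  sim <- simulateBioid(n_proteins = 20, n_true = 5, n_isoform_pairs = 2,
                       seed = 11)
  f <- tempfile(); fm <- tempfile()
  writePeptideTable(sim$peptides, f, fm)
  back <- readPeptideTable(f, fm)
  expect_identical(rowData(back)$peptide_sequence,
                   rowData(sim$peptides)$peptide_sequence)
  expect_identical(rowData(back)$protein_id,
                   rowData(sim$peptides)$protein_id)
  expect_equal(assay(back, "intensity"), assay(sim$peptides, "intensity"),
               tolerance = 1e-12)
  expect_identical(is.na(assay(back, "intensity")),
                   is.na(assay(sim$peptides, "intensity")))
})

test_that("gene lists dedupe case-insensitively and skip comments", {
  f <- tempfile()
  writeLines(c("# curated junction proteins", "CTNNB1", "JUP", "ctnnb1"), f)
  gl <- readGeneList(f)
  expect_equal(gl, c("CTNNB1", "JUP"))
  n <- 37
  writeLines(sprintf("G%03d", seq_len(n)), f)
  expect_length(readGeneList(f), n)       # line-count oracle
  writeLines("# only a comment", f)
  expect_warning(gl <- readGeneList(f), "empty")
  expect_length(gl, 0)
})

test_that("edge lists collapse duplicates, drop self-loops, accept SIF", {
  f <- tempfile()
  writeLines(c("A\tB", "B\tA"), f)
  g <- readEdgeList(f)
  expect_equal(igraph::ecount(g), 1)
  writeLines(c("A\tB", "A\tA"), f)
  expect_warning(g <- readEdgeList(f), "self-loop")
  expect_equal(igraph::ecount(g), 1)
  writeLines("A\tpp\tB", f)               # SIF dialect, middle ignored
  g <- readEdgeList(f)
  expect_true(igraph::are_adjacent(g, "A", "B"))
  writeLines("A", f)
  expect_error(readEdgeList(f), "fewer than 2")
})

test_that("readers are row-order independent up to row order", {
  f1 <- tempfile(); f2 <- tempfile()
  writeLines(c("A\tB", "C\tD", "B\tC"), f1)
  writeLines(c("B\tC", "A\tB", "C\tD"), f2)
  g1 <- readEdgeList(f1); g2 <- readEdgeList(f2)
  el <- function(g) {
    e <- igraph::as_edgelist(g)
    sorted <- t(apply(e, 1, sort))
    sorted[order(sorted[, 1], sorted[, 2]), ]
  }
  expect_equal(el(g1), el(g2))
})

test_that("expression matrices and FRAP traces round-trip", {
  m <- matrix(runif(12), 3, 4,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  f <- tempfile()
  writeExpressionMatrix(m, f)
  expect_equal(readExpressionMatrix(f), m, tolerance = 1e-12)
  tr <- data.frame(time_s = 0:5, intensity = runif(6))
  write.table(tr, f, sep = "\t", quote = FALSE, row.names = FALSE)
  got <- readFrapTrace(f)
  expect_equal(got$intensity, tr$intensity, tolerance = 1e-12)
})
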