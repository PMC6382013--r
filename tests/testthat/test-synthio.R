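test_that("generators are bit-reproducible for a fixed seed", {
  a <- simulateBioid(n_proteins = 50, n_true = 10, seed = 5)
  b <- simulateBioid(n_proteins = 50, n_true = 10, seed = 5)
  expect_identical(assay(a$peptides, "intensity"),
                   assay(b$peptides, "intensity"))
  expect_identical(a$truth$true_interactors, b$truth$true_interactors)
  e1 <- simulateExpressionMatrix(50, c("heart", "brain", "liver"), "heart",
                                 c(exclusive = 5), noise_sd = 0.2, seed = 5)
  e2 <- simulateExpressionMatrix(50, c("heart", "brain", "liver"), "heart",
                                 c(exclusive = 5), noise_sd = 0.2, seed = 5)
  expect_identical(e1$fpkm, e2$fpkm)
  g1 <- simulateTierGraph(c(3, 4, 5, 2), 3, seed = 5)
  g2 <- simulateTierGraph(c(3, 4, 5, 2), 3, seed = 5)
  expect_identical(igraph::as_edgelist(g1$graph),
                   igraph::as_edgelist(g2$graph))
  f1 <- simulateFrapCurve(0.5, 0.3, 20, 300, seed = 5)
  f2 <- simulateFrapCurve(0.5, 0.3, 20, 300, seed = 5)
  expect_identical(f1, f2)
})

test_that("bioid generator honors its configuration contracts", {
  expect_error(simulateBioid(n_proteins = 5, n_true = 6), "n_true")
  null <- simulateBioid(n_proteins = 30, n_true = 0, seed = 1)
  expect_length(null$truth$true_interactors, 0)
  sim <- simulateBioid(n_proteins = 60, n_true = 12, n_isoform_pairs = 3,
                       seed = 2)
  expect_length(sim$truth$true_interactors, 12)
  rd <- rowData(sim$peptides)
  # true interactors never single-peptide; exact single-peptide count
  npep <- table(rd$protein_id)
  expect_true(all(npep[sim$truth$true_interactors] >= 2))
  expect_length(sim$truth$single_peptide, round(0.779 * (60 - 12)))
  # isoform pairs collapse gene symbols among true interactors
  expect_equal(length(unique(rd$gene_symbol)), 60 - 3)
  # sequences digest back to exactly the peptides in the table
  pep_of <- split(as.character(rd$peptide_sequence), rd$protein_id)
  for (p in names(pep_of)[1:10]) {
    dig <- digestSequence(as.character(sim$sequences[[p]]),
                          min_len = 7, max_len = 30)
    expect_setequal(dig, unique(pep_of[[p]]))
  }
})

test_that("simulated intensities match configured distribution at scale", {
  sim <- simulateBioid(n_proteins = 1200, n_true = 0,
                       peptides_per_protein = c(1, 1),
                       single_peptide_fraction = 1,
                       baseline_log2_mean = 25, baseline_log2_sd = 2,
                       peptide_log2_sd = 0, replicate_noise_sd = 0.4,
                       missing_rate = 0.1, seed = 3)
  x <- assay(sim$peptides, "intensity")
  n <- length(x)
  miss <- mean(is.na(x))
  expect_lt(abs(miss - 0.1), 3 * sqrt(0.1 * 0.9 / n))
  l <- log2(x[!is.na(x)])
  sd_tot <- sqrt(2^2 + 0.4^2)            # protein spread + replicate noise
  expect_lt(abs(mean(l) - 25), 3 * sd_tot / sqrt(length(l)))
  expect_lt(abs(sd(l) - sd_tot), 3 * sd_tot / sqrt(2 * length(l)))
})

test_that("a strong clean spike is recovered exactly by the pipeline", {
  sim <- simulateBioid(n_proteins = 80, n_true = 15, spike_log2fc = 10,
                       replicate_noise_sd = 0.01, missing_rate = 0,
                       single_peptide_fraction = 0.3, n_isoform_pairs = 0,
                       seed = 4)
  hits <- selectHits(testEnrichment(filterSinglePeptide(
    rollupPeptides(sim$peptides))))
  expect_setequal(as.character(hits$protein_id),
                  sim$truth$true_interactors)
})

test_that("expression generator plants patterns the classifier recovers", {
  tiss <- c("heart", "brain", "liver", "kidney", "lung", "muscle")
  ex <- simulateExpressionMatrix(60, tiss, "heart",
                                 c(exclusive = 5, multi_high = 5,
                                   gradient = 5), seed = 6)
  expect_equal(sum(ex$truth == "exclusive"), 5)
  # exclusive genes express above floor only in the target
  for (g in names(ex$truth)[ex$truth == "exclusive"])
    expect_true(ex$fpkm[g, "heart"] >= 1 &&
                all(ex$fpkm[g, setdiff(tiss, "heart")] < 1))
  calls <- callEnrichedGenes(ex$fpkm, ex$tissue, ex$target)
  got <- setNames(as.character(calls$calls$pattern), calls$calls$gene)
  expect_identical(got[names(ex$truth)], ex$truth)   # zero-noise exactness
  empty <- simulateExpressionMatrix(40, tiss, "heart", seed = 7)
  c2 <- callEnrichedGenes(empty$fpkm, empty$tissue, empty$target)
  expect_length(c2$enriched, 0)
  expect_error(simulateExpressionMatrix(10, tiss, "bone"), "target")
})

test_that("tier graph plants BFS distances equal to tiers", {
  star <- simulateTierGraph(c(3, 0, 0, 0), 0, seed = 8)
  a <- assignTiers(star$graph, star$seed_name)
  expect_equal(sum(a$tier == "primary"), 3)
  expect_true(all(a$tier[a$tier != "seed"] == "primary"))
  tg <- simulateTierGraph(c(4, 6, 8, 3), 5, extra_edge_prob = 0.3, seed = 9)
  for (nm in names(tg$truth)) {
    expect_equal(unname(tg$truth[nm]), switch(
      as.character(igraph::distances(tg$graph, v = tg$seed_name,
                                     to = nm)[1, 1]),
      "0" = "seed", "1" = "primary", "2" = "secondary", "3" = "tertiary",
      "4" = "quaternary", "Inf" = "unconnected"))
  }
  expect_equal(sum(!is.finite(igraph::distances(
    tg$graph, v = tg$seed_name)[1, ])), 5)
})

test_that("frap generator follows the double-exponential recovery law", {
  z <- simulateFrapCurve(0, 0.5, 20, 300, noise_sd = 0, seed = 10)
  expect_true(all(z$intensity == 0))
  long <- simulateFrapCurve(0.6, 0.5, 5, 10, dt = 10, duration = 2000,
                            noise_sd = 0, seed = 10)
  expect_equal(tail(long$intensity, 1), 0.6, tolerance = 1e-6)
  half <- simulateFrapCurve(0.8, 0, 20, 100, dt = 50, duration = 200,
                            noise_sd = 0)
  expect_equal(half$intensity[half$time == 100], 0.4, tolerance = 1e-12)
  expect_equal(half$intensity[1], 0)
  expect_error(simulateFrapCurve(0.5, duration = 1, dt = 5), "duration")
  expect_error(simulateFrapCurve(1.5), "mobile_fraction")
})
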