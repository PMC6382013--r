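# Synthetic-data generators with known ground truth for every pipeline
# stage.  Defaults emulate the study design they stand in for: 917 detected
# proteins of which 365 are genuine bait-proximal interactors spiked at
# 20-fold, six bait and six control replicates, ~30% replicate CV
# (log2 sd 0.42), 10% missing cells, and enough single-peptide background
# identifications that the single-peptide exclusion removes 430 proteins.

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Random tryptic-like peptide: starts with a non-K/R/P residue, no internal
# K/R, ends in K or R.  Concatenating a protein's peptides therefore yields a
# sequence whose 0-missed-cleavage digest is exactly that peptide set.
.random_peptides <- function(n, min_len = 7L, max_len = 20L) {
  body_aa <- strsplit(gsub("[KR]", "", .AA20), "")[[1]]
  first_aa <- setdiff(body_aa, "P")
  len <- sample(min_len:max_len, n, replace = TRUE)
  gen <- function(len) {
    k <- length(len)
    mid <- sample(body_aa, sum(len) - 2L * k, replace = TRUE)
    grp <- factor(rep(seq_len(k), len - 2L), levels = seq_len(k))
    mids <- vapply(split(mid, grp), paste, character(1), collapse = "")
    paste0(sample(first_aa, k, replace = TRUE), mids,
           sample(c("K", "R"), k, replace = TRUE))
  }
  out <- gen(len)
  while (anyDuplicated(out)) {
    i <- which(duplicated(out))
    out[i] <- gen(len[i])
  }
  out
}

#' Simulate a bait-vs-control proximity-labeling experiment
#'
#' Generates a peptide-level intensity table with log2-normal intensities, a
#' spiked set of true interactors, MCAR (or intensity-dependent) missingness,
#' a configurable fraction of single-peptide background identifications, and
#' matching protein sequences (each protein sequence is the concatenation of
#' its tryptic peptides, so an in-silico digest recovers exactly the peptides
#' in the table).
#'
#' True interactors always carry at least two peptides — genuine bait-proximal
#' proteins are assumed well covered — so the single-peptide exclusion acts on
#' background proteins only.  \code{single_peptide_fraction} is the fraction
#' of background proteins given exactly one peptide (an exact count, not a
#' Bernoulli draw, so the identification funnel is deterministic).  Isoform
#' pairs among the true interactors share a gene symbol, reproducing the
#' protein-to-gene collapse of real hit lists.
#'
#' @param n_proteins total detected proteins (default 917).
#' @param n_true spiked true interactors (default 365).
#' @param peptides_per_protein integer range (min, max) of peptides for
#'   multi-peptide proteins (default \code{c(2, 18)}).
#' @param n_bait,n_control replicate counts (defaults 6 and 6).
#' @param baseline_log2_mean,baseline_log2_sd protein base abundance on the
#'   log2 scale (defaults 25 and 2).
#' @param peptide_log2_sd per-peptide ionization-efficiency spread (log2 sd,
#'   default 1).
#' @param spike_log2fc log2 fold-change added to bait-group intensities of
#'   true interactors (default \code{log2(20)}).
#' @param replicate_noise_sd replicate noise, log2 units (default 0.42,
#'   approximately a 30\% coefficient of variation).
#' @param missing_rate per-cell missingness probability (default 0.1).
#' @param missing_mode \code{"mcar"} (default) or \code{"logistic"}
#'   (low-intensity cells more likely missing; same marginal rate).
#' @param single_peptide_fraction fraction of background proteins with exactly
#'   one peptide (default 0.779, i.e. 430 of the 552 background proteins when
#'   \code{n_proteins = 917} and \code{n_true = 365}).
#' @param n_isoform_pairs pairs of true-interactor proteins sharing one gene
#'   symbol (default 11, so 365 hit proteins collapse to 354 genes).
#' @param seed RNG seed; the caller's RNG state is restored on exit.
#' @return list with \code{peptides} (a \linkS4class{PeptideExperiment}),
#'   \code{sequences} (\code{AAStringSet} named by protein id) and
#'   \code{truth} (list: \code{true_interactors}, \code{single_peptide},
#'   \code{spike_log2fc}, per-protein base abundances).
#' @export
simulateBioid <- function(n_proteins = 917L, n_true = 365L,
                          peptides_per_protein = c(2L, 18L),
                          n_bait = 6L, n_control = 6L,
                          baseline_log2_mean = 25, baseline_log2_sd = 2,
                          peptide_log2_sd = 1,
                          spike_log2fc = log2(20),
                          replicate_noise_sd = 0.42,
                          missing_rate = 0.1,
                          missing_mode = c("mcar", "logistic"),
                          single_peptide_fraction = 0.779,
                          n_isoform_pairs = 11L,
                          seed = NULL) {
  missing_mode <- match.arg(missing_mode)
  if (n_true > n_proteins) stop("n_true must be <= n_proteins")
  if (missing_rate < 0 || missing_rate > 1 ||
      single_peptide_fraction < 0 || single_peptide_fraction > 1)
    stop("probabilities must lie in [0, 1]")
  if (n_bait < 2L || n_control < 2L) stop("need >= 2 replicates per group")
  .with_seed(seed, {
    prot <- sprintf("P%04d", seq_len(n_proteins))
    gene <- sprintf("G%04d", seq_len(n_proteins))
    true_idx <- sort(sample.int(n_proteins, n_true))
    # isoform pairs among true interactors share the first member's symbol
    n_iso <- min(n_isoform_pairs, n_true %/% 2L)
    if (n_iso > 0L) {
      a <- true_idx[seq_len(n_iso)]
      b <- true_idx[n_iso + seq_len(n_iso)]
      gene[b] <- gene[a]
    }
    bg_idx <- setdiff(seq_len(n_proteins), true_idx)
    n_single <- round(single_peptide_fraction * length(bg_idx))
    single_idx <- sort(sample(bg_idx, n_single))
    npep <- integer(n_proteins)
    npep[single_idx] <- 1L
    multi <- setdiff(seq_len(n_proteins), single_idx)
    npep[multi] <- sample(peptides_per_protein[1L]:peptides_per_protein[2L],
                          length(multi), replace = TRUE)

    pidx <- rep(seq_len(n_proteins), npep)
    total_pep <- length(pidx)
    base <- rnorm(n_proteins, baseline_log2_mean, baseline_log2_sd)
    pep_mu <- base[pidx] + rnorm(total_pep, 0, peptide_log2_sd)
    n_samp <- n_bait + n_control
    mu <- matrix(pep_mu, total_pep, n_samp)
    is_true_pep <- pidx %in% true_idx
    mu[is_true_pep, seq_len(n_bait)] <-
      mu[is_true_pep, seq_len(n_bait)] + spike_log2fc
    x <- 2^(mu + matrix(rnorm(total_pep * n_samp, 0, replicate_noise_sd),
                        total_pep, n_samp))
    if (missing_rate > 0) {
      if (missing_mode == "mcar") {
        drop <- matrix(runif(total_pep * n_samp) < missing_rate,
                       total_pep, n_samp)
      } else {
        lx <- log2(x)
        p <- 2 * missing_rate * stats::plogis(-(lx - median(lx)))
        drop <- matrix(runif(total_pep * n_samp) < p, total_pep, n_samp)
      }
      x[drop] <- NA_real_
    }
    colnames(x) <- c(sprintf("bait_%d", seq_len(n_bait)),
                     sprintf("ctrl_%d", seq_len(n_control)))
    peptides <- data.frame(
      peptide_sequence = .random_peptides(total_pep),
      protein_id = prot[pidx],
      gene_symbol = gene[pidx],
      stringsAsFactors = FALSE)
    samples <- data.frame(
      group = rep(c("bait", "control"), c(n_bait, n_control)),
      replicate = c(seq_len(n_bait), seq_len(n_control)),
      row.names = colnames(x))
    seqs <- vapply(split(peptides$peptide_sequence, pidx), paste,
                   character(1), collapse = "")
    seqs <- Biostrings::AAStringSet(setNames(seqs[as.character(
      seq_len(n_proteins))], prot))
    list(
      peptides = PeptideExperiment(x, peptides, samples),
      sequences = seqs,
      truth = list(true_interactors = prot[true_idx],
                   single_peptide = prot[single_idx],
                   spike_log2fc = spike_log2fc,
                   base_log2 = setNames(base, prot)))
  })
}

#' Simulate an FPKM matrix with planted tissue-enrichment patterns
#'
#' Plants genes that satisfy one of the three enrichment patterns with a
#' comfortable margin (see \code{\link{classifyPattern}}) and background genes
#' that satisfy none, then optionally multiplies every cell by log-normal
#' noise.
#'
#' @param n_genes total genes.
#' @param tissue_labels character vector of tissue names (one sample each).
#' @param target the tissue the patterns are anchored on (must be in
#'   \code{tissue_labels}).
#' @param pattern_counts named integer vector with any of
#'   \code{exclusive}, \code{multi_high}, \code{gradient}; the rest of the
#'   genes are background.
#' @param fc_threshold,floor classifier parameters the planting respects
#'   (defaults 2 and 1 FPKM).
#' @param noise_sd log-normal noise sd (natural log scale; default 0, i.e.
#'   noiseless).
#' @param seed RNG seed.
#' @return list with \code{fpkm} (genes x tissues matrix), \code{tissue}
#'   (sample to tissue labels), \code{target} and \code{truth} (named pattern
#'   per gene, \code{"none"} for background).
#' @export
simulateExpressionMatrix <- function(n_genes, tissue_labels, target,
                                     pattern_counts = c(exclusive = 0L,
                                                        multi_high = 0L,
                                                        gradient = 0L),
                                     fc_threshold = 2, floor = 1,
                                     noise_sd = 0, seed = NULL) {
  if (!target %in% tissue_labels) stop("target tissue absent from labels")
  known <- c("exclusive", "multi_high", "gradient")
  if (!all(names(pattern_counts) %in% known))
    stop("unknown pattern name(s)")
  counts <- setNames(integer(3), known)
  counts[names(pattern_counts)] <- as.integer(pattern_counts)
  if (sum(counts) > n_genes) stop("pattern counts exceed n_genes")
  nt <- length(tissue_labels)
  ti <- match(target, tissue_labels)
  .with_seed(seed, {
    truth <- rep("none", n_genes)
    m <- matrix(0, n_genes, nt, dimnames = list(
      sprintf("GENE%05d", seq_len(n_genes)), tissue_labels))
    slots <- sample.int(n_genes)          # random row placement
    k <- 0L
    take <- function(n) { r <- slots[k + seq_len(n)]; k <<- k + n; r }
    # exclusive: target well above floor, every other tissue well below
    if (counts["exclusive"] > 0L) {
      r <- take(counts["exclusive"])
      truth[r] <- "exclusive"
      m[r, ] <- matrix(runif(length(r) * nt, 0, 0.2 * floor),
                       length(r), nt)
      m[r, ti] <- runif(length(r), 20, 80)
    }
    # multi_high: 2-4 tissues (incl. target) near a common high level, all
    # others at least 2*fc below the lowest high tissue
    if (counts["multi_high"] > 0L) {
      r <- take(counts["multi_high"])
      truth[r] <- "multi_high"
      for (g in r) {
        n_high <- sample(2:min(4L, nt), 1L)
        hi <- c(ti, sample(setdiff(seq_len(nt), ti), n_high - 1L))
        H <- runif(1, 30, 60)
        v <- runif(nt, 0.02 * H, 0.1 * H)
        v[hi] <- H * runif(n_high, 0.9, 1.1)
        m[g, ] <- v
      }
    }
    # gradient: target the single maximum, max/min ratio 8-16 (margin over 4)
    if (counts["gradient"] > 0L) {
      r <- take(counts["gradient"])
      truth[r] <- "gradient"
      for (g in r) {
        M <- runif(1, 30, 60)
        v <- runif(nt, M / 16, M / 8)
        v[ti] <- M
        m[g, ] <- v
      }
    }
    # background: flat, above floor, dynamic range < 4, >4 'high' tissues
    bg <- slots[k + seq_len(n_genes - sum(counts))]
    m[bg, ] <- matrix(runif(length(bg) * nt, 2, 5), length(bg), nt)
    if (noise_sd > 0)
      m <- m * exp(matrix(rnorm(n_genes * nt, 0, noise_sd), n_genes, nt))
    list(fpkm = m,
         tissue = setNames(tissue_labels, tissue_labels),
         target = target,
         truth = setNames(truth, rownames(m)))
  })
}

#' Simulate an interaction graph with planted tiers around a seed
#'
#' Builds a graph in which the breadth-first distance from the seed equals the
#' planted tier for every connected node: each tier-k node receives at least
#' one edge to a tier-(k-1) node, and extra edges are added only within a tier
#' or between adjacent tiers, which can never shorten a shortest path below
#' the planted tier.  Unconnected nodes have no path to the seed (they may be
#' linked to each other).
#'
#' @param tier_sizes integer vector of four tier sizes
#'   (primary, secondary, tertiary, quaternary); default the study-scale
#'   \code{c(11, 62, 177, 48)}.
#' @param n_unconnected nodes with no path to the seed (default 52).
#' @param extra_edge_prob probability of each admissible extra edge
#'   (default 0.02).
#' @param seed_name node name of the bait (default \code{"BAIT"}).
#' @param seed RNG seed.
#' @return list with \code{graph} (igraph), \code{seed_name} and
#'   \code{truth} (named tier label per node, the seed labeled
#'   \code{"seed"}).
#' @export
simulateTierGraph <- function(tier_sizes = c(11L, 62L, 177L, 48L),
                              n_unconnected = 52L,
                              extra_edge_prob = 0.02,
                              seed_name = "BAIT", seed = NULL) {
  if (length(tier_sizes) != 4L || any(tier_sizes < 0L))
    stop("tier_sizes must be four non-negative integers")
  .with_seed(seed, {
    tiers <- c("primary", "secondary", "tertiary", "quaternary")
    nodes <- list(seed_name)
    labels <- c(seed = seed_name)
    truth <- c()
    for (k in 1:4) {
      nm <- if (tier_sizes[k] > 0L)
        sprintf("T%d_%03d", k, seq_len(tier_sizes[k])) else character(0)
      nodes[[k + 1L]] <- nm
      truth <- c(truth, setNames(rep(tiers[k], length(nm)), nm))
    }
    unc <- if (n_unconnected > 0L)
      sprintf("U_%03d", seq_len(n_unconnected)) else character(0)
    truth <- c(setNames("seed", seed_name), truth,
               setNames(rep("unconnected", length(unc)), unc))
    edges <- matrix(character(0), ncol = 2)
    for (k in 1:4) {
      cur <- nodes[[k + 1L]]
      prev <- nodes[[k]]
      if (length(cur) == 0L) next
      if (length(prev) == 0L)
        stop("tier ", k, " is non-empty but tier ", k - 1L, " is empty")
      edges <- rbind(edges,
                     cbind(cur, sample(prev, length(cur), replace = TRUE)))
      # extra edges: within the tier and to the previous tier
      cand <- rbind(
        if (length(cur) > 1L) t(utils::combn(cur, 2L)),
        as.matrix(expand.grid(cur, prev, stringsAsFactors = FALSE)))
      if (!is.null(cand) && nrow(cand) > 0L && extra_edge_prob > 0) {
        keep <- runif(nrow(cand)) < extra_edge_prob
        edges <- rbind(edges, cand[keep, , drop = FALSE])
      }
    }
    if (length(unc) > 1L && extra_edge_prob > 0) {
      cand <- t(utils::combn(unc, 2L))
      keep <- runif(nrow(cand)) < extra_edge_prob
      edges <- rbind(edges, cand[keep, , drop = FALSE])
    }
    g <- igraph::graph_from_edgelist(as.matrix(edges), directed = FALSE)
    g <- igraph::simplify(g)
    iso <- setdiff(names(truth), igraph::V(g)$name)
    g <- igraph::add_vertices(g, length(iso), name = iso)
    list(graph = g, seed_name = seed_name, truth = truth)
  })
}

#' Simulate a FRAP recovery curve
#'
#' Generates \deqn{F(t) = M [a (1 - 2^{-t/t_f}) + (1-a)(1 - 2^{-t/t_s})]}
#' plus Gaussian noise, sampled at \code{dt} on \code{[0, duration]}.
#' \code{F(0) = 0} before noise; the plateau is the mobile fraction \code{M}.
#'
#' @param mobile_fraction plateau recovery fraction \code{M} in [0, 1].
#' @param fast_fraction fraction \code{a} of the mobile pool recovering with
#'   the fast halftime (set 1 for a single-exponential curve).
#' @param t_half_fast,t_half_slow pool recovery halftimes, seconds.
#' @param dt frame interval, seconds (default 5).
#' @param duration acquisition length, seconds (default 600).
#' @param noise_sd Gaussian noise sd on the normalized scale (default 0.02).
#' @param seed RNG seed.
#' @return data.frame with columns \code{time}, \code{intensity}.
#' @export
simulateFrapCurve <- function(mobile_fraction, fast_fraction = 1,
                              t_half_fast = 20, t_half_slow = 300,
                              dt = 5, duration = 600,
                              noise_sd = 0.02, seed = NULL) {
  if (mobile_fraction < 0 || mobile_fraction > 1)
    stop("mobile_fraction must lie in [0, 1]")
  if (fast_fraction < 0 || fast_fraction > 1)
    stop("fast_fraction must lie in [0, 1]")
  if (t_half_fast <= 0 || t_half_slow <= 0) stop("halftimes must be > 0")
  if (duration < dt) stop("duration must be >= dt")
  .with_seed(seed, {
    t <- seq(0, duration, by = dt)
    f <- mobile_fraction *
      (fast_fraction * (1 - 2^(-t / t_half_fast)) +
       (1 - fast_fraction) * (1 - 2^(-t / t_half_slow)))
    data.frame(time = t,
               intensity = f + rnorm(length(t), 0, noise_sd))
  })
}
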