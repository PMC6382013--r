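---
title: "proxitome: methods and design notes"
author: "proxitome authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{proxitome: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proxitome)
```

# The analysis problem

Proximity-dependent biotinylation (BioID) fused to a junctional bait — here
modeled on N-cadherin (CDH2) at the cardiomyocyte adherens junction — labels
proteins within roughly 10 nm of the bait.  Streptavidin capture followed by
label-free LC-MS/MS of bait and control replicates yields peptide-level
intensity tables.  The analysis task is to decide, per protein, whether its
abundance in the bait channel exceeds the control background strongly and
reproducibly enough to call it an interactome member, and then to
characterize that interactome: how abundant each member is (iBAQ), how the
member set compares with reference interactomes and curated compartment
lists, whether members are preferentially encoded by tissue-enriched genes,
how they arrange into interaction tiers around the bait, and how mobile the
core components are at the junction (FRAP).

`proxitome` implements that chain as composable, tested stages over
Bioconductor containers (`SummarizedExperiment` subclasses for peptide and
protein tables, `igraph` for networks, `Biostrings` for sequences), plus a
synthetic-data generator that produces inputs with known ground truth for
every stage.

# Enrichment selection

## Model and statistic

Peptide intensities are rolled up to proteins by per-sample summation; a
protein cell is missing only when all of its peptides are missing in that
sample.  Proteins identified by a single distinct peptide sequence are
excluded (`min_peptides = 2`), mirroring standard practice for label-free
interactome calling.

Per protein, a two-sided equal-variance Student's *t*-test compares
log2-transformed intensities between the bait and control groups.  The fold
change is the ratio of raw group means; hits satisfy jointly

$$\mathrm{FC} \ge 10 \quad\text{and}\quad P < 0.001 .$$

The fold-change threshold is *inclusive* (the boundary value 10 is a hit).
No multiple-testing correction is applied on the selection path — the raw
$P < 0.001$ rule is the documented convention for this assay class — but
Benjamini–Hochberg q-values are reported as an extra column.

## Missing values

Missing intensities are encoded as `NA`, strictly distinct from measured
zeros.  Before testing, the default policy (`impute = "floor"`) replaces
missing cells — and measured values below the floor, including zeros — by
half the smallest nonzero observed intensity, identically in both groups.
This keeps bait-only proteins testable with a finite fold change.  An
`"exclude"` mode drops missing cells instead and flags proteins with fewer
than two usable values per group as untestable.

The floor policy has a knowable side effect: imputed floors are low
outliers, so they inflate the pooled variance and push *P*-values upward.
The null tail is therefore slightly *conservative* under missingness, never
anticonservative.  Consequently the package's calibration check runs the
null simulation without missingness (where the log2-normal null makes the
*t* statistic exactly calibrated, and 200 simulated 487-protein experiments
put the $P<0.001$ rate within three binomial standard errors of 0.001), and
a separate assertion verifies that switching default missingness back on
only lowers that rate.

## Permutation cross-check

With six bait and six control replicates the exact permutation distribution
of the *t* statistic has only $\binom{12}{6} = 924$ support points.  A
mid-range *t*-reference *P*-value can differ from the exact permutation
*P*-value by up to about 0.1 purely through this discreteness — no estimator
can close that gap.  The test suite therefore checks two things separately:
a $10^5$-draw Monte-Carlo permutation estimate must agree with the exact
enumeration within Monte-Carlo error (the sharp check), and the *t*
*P*-value must agree with the permutation estimate within Monte-Carlo error
plus a 0.10 finite-sample allowance.

# iBAQ abundance

iBAQ divides a protein's summed intensity by its count of theoretically
observable tryptic peptides.  The in-silico digest cleaves C-terminal to K
or R, not before proline (configurable), with 0 missed cleavages and an
observable window of 7–30 residues by default.  The published search
settings fix only the 7-residue minimum; the remaining divisor parameters
are not public, so the defaults above are a documented, reproducible
surrogate and every parameter is an argument.  The reported `delta_ibaq` is
the bait-average minus control-average iBAQ over observed replicates;
missing replicates are excluded from the means rather than imputed, and the
value may legitimately be negative.

# Interactome comparison

`partitionSets()` computes all disjoint Venn regions over 2–3 named gene
sets (case-insensitive membership, original spellings preserved).
`categoryDistribution()` distributes a member set over a
one-category-per-gene vocabulary by count or by abundance weight (negative
delta-iBAQ clipped to zero).  `fisherOverrep()` tests overrepresentation of
a member set among enriched genes within a stated universe; the default
one-sided "greater" *P* is the hypergeometric tail $P(X \ge a)$, and the
odds ratio is the sample $ad/bc$.  The universe must be supplied explicitly
(default in the pipeline: the gene set of the expression matrix used to
call enrichment) because overrepresentation conclusions are universe-
dependent.

# Tissue expression patterns

Genes are called tissue-enriched from an FPKM matrix by three rules,
evaluated per gene on tissue-averaged profiles in precedence order
(most to least specific); `fc_threshold = 2`, expression floor 1 FPKM:

1. **exclusive** — expressed ($\ge$ floor) in the target tissue and below
   floor everywhere else;
2. **multi_high** — the "high" set (tissues within `fc_threshold`-fold of
   the gene's maximum) contains the target and has 2–4 members, the sum of
   FPKM exceeds the number of tissues, and every high tissue is at least
   `fc_threshold`-fold above every non-high tissue;
3. **gradient** — the target holds the single maximum and the max/min ratio
   is at least 4.

Design notes: the published rule system leaves the expression floor and the
exact "high set" construction to an external tool, so both are fixed here as
documented defaults and exposed as arguments.  The lower bound of 2 on the
high-set size is deliberate — "multiple high tissues" read literally —
because without it any single-peaked gene would be captured by rule 2 before
rule 3 could apply, and the gradient class would be empty.  Ratio criteria
are scale-invariant; the floor and sum-FPKM criteria are intentionally
scale-dependent (FPKM units carry meaning).

The generator plants each pattern with margin (exclusive: target 20–80 FPKM
against a background below 0.2; multi_high: high tissues within 1.1/0.9 of a
common level, ten-fold above the low tissues; gradient: max/min planted at
8–16) and background genes that satisfy no rule.  At zero noise recovery is
exact by construction; under multiplicative log-normal noise with sd 0.25
the planted-label recovery observed in the test suite is about 95%,
dominated by multi_high genes whose high set collapses under noise.

# Network tiers

The hierarchical interactor classification — primary binds the bait,
secondary binds primary but not the bait, tertiary binds secondary,
quaternary is everything farther that still reaches the bait — is exactly
breadth-first distance from the seed with $d \ge 4$ collapsed, and is
implemented as such (a node adjacent to both the seed and a primary node is
primary: minimum distance wins).  Members with no path to the seed are
"unconnected".  Edges involving non-member nodes are discarded before
layering by default; `keep_bridges = TRUE` retains them for distance
computation while excluding them from the reported counts.  The
implementation is an explicit frontier-expansion BFS; the test suite checks
it against an independent shortest-path oracle on random graphs and on a
planted study-scale graph (tiers 11/62/177/48 plus 52 unconnected).

# FRAP kinetics

Raw traces are normalized full-scale,
$F_{norm}(t) = (F(t) - F_{bleach})/(F_{pre} - F_{bleach})$, with time
rebased to the bleach frame; no acquisition-bleaching reference correction
is applied (negligible over 10 min at the modeled frame rates).  The fitted
model partitions the mobile pool $M$ between fast and slow components,

$$F(t) = M\left[a\,(1 - e^{-k_f t}) + (1-a)\,(1 - e^{-k_s t})\right],
\qquad t_{1/2} = \ln 2 / k,$$

with $a = 1$ for the single-exponential model.  Fitting is bounded
Levenberg–Marquardt least squares with five deterministic starts spanning
halftime decades 10–1000 s; the lowest-SSE converged fit wins, and the
fast/slow roles are enforced by swapping.  Mobile fractions above 1 are
flagged (`super_recovery`) rather than rejected.

**Identifiability.** A slow halftime can only be estimated from a window
that samples enough of the plateau.  A Cramér–Rao analysis of the double
model at junctional-complex parameters ($M = 0.344$, $a = 0.27$,
$t_{1/2}$ 24.9/315.2 s, per-point noise 0.02 at 5 s sampling) gives
$\sigma(M) \approx 0.053$ and $\sigma(t_{1/2,\mathrm{slow}})/t_{1/2}
\approx 46\%$ over a 600 s window, but $\sigma(M) \approx 0.003$ and
$\approx 6\%$ over 1260 s ($\ge 4$ slow halftimes).  The package's
single-curve recovery benchmark therefore uses a 1260 s window for the slow
double-exponential regime; the single-exponential regime ($M = 0.75$,
$t_{1/2} = 97$ s) is comfortably identifiable within the standard 600 s
window.  Fitting the *mean* of ~50 noisy traces — the usual pooled-contact
practice, and what `scripts/acceptance.R` does — reduces the effective noise
by $\sqrt{50}$ and makes the 600 s window adequate again.

# Synthetic data: what it emulates, and what it does not

The generator defaults are the emulated study design: 917 detected proteins
of which 365 are genuine interactors spiked at 20-fold ($\log_2 20 \approx
4.32$); six bait and six control replicates; protein base abundance
$\log_2 \sim \mathcal{N}(25, 2^2)$ with per-peptide offsets
$\mathcal{N}(0,1)$ and replicate noise sd 0.42 log2 units (approximately a
30% coefficient of variation); 10% missing cells (MCAR by default, an
intensity-dependent logistic mode available); enough single-peptide
background identifications (fraction 0.779 of the 552 background proteins,
i.e. 430) that the single-peptide exclusion funnel reproduces
917 → 487; and 11 isoform pairs among the true interactors so 365 hit
proteins collapse to 354 genes.  True interactors always carry at least two
peptides, modeling the empirical fact that genuine bait-proximal proteins
are well covered; the single-peptide exclusion therefore acts on background
only.  Protein sequences are emitted as the concatenation of each protein's
tryptic peptides, so the in-silico digest recovers exactly the peptide set
— a deliberate closure that makes the iBAQ divisor exact on synthetic data.

What the generator does *not* model: peptide detectability and ionization
bias beyond a static per-peptide offset, retention-time structure,
between-run normalization drift, correlated (batch) noise, and protein
inference ambiguity (each peptide maps to one protein).  Passing tests on
synthetic data therefore demonstrate the correctness and calibration of the
statistical machinery under the stated model, not robustness to every
artifact of real MS data.

Problem sizes used by the test suite and acceptance script — 200 null
simulations of 487 proteins, 50 spiked simulations at study scale, 50
synthetic FRAP curves per regime, 20 noisy expression matrices of 300 genes,
100 random graphs up to 200 nodes, and the exhaustive Fisher check over all
2×2 tables with $N \le 60$ — were chosen so each suite completes in about a
minute while leaving Monte-Carlo error well below the tolerance it checks.

# Numerical and edge-case conventions

* Identifiers are compared upper-cased; original spellings are reported.
* Identical bait/control groups give $P = 1$ (not `NaN`); zero pooled
  variance with a nonzero difference gives $P = 0$.
* `fold_change` $= 2^{\mathrm{log2fc}}$ to within $10^{-9}$ relative by
  construction.
* A digest with zero observable peptides flags the protein
  (`no_observable_peptide`) instead of producing an infinite iBAQ.
* Venn regions use canonical (sorted) name signatures, so partitions are
  order-invariant in the input sets.
* Tier assignment sorts output rows by tier then node name, making results
  independent of node enumeration order.
* Flat FRAP traces short-circuit to $M$ = plateau with a `flat_trace` flag
  rather than entering the optimizer.

# Known limitations

* The enrichment path trusts the input peptide-to-protein assignment; no
  razor-peptide or protein-inference logic.
* No between-run intensity normalization; intensities are taken as given.
* The published tissue-enrichment gene catalogs depend on external RNA-seq
  compendia and unpublished classifier internals; this package reproduces
  the rule system, not those catalogs.
* Tier layering is only as good as the supplied edge list; no interaction
  knowledge base is bundled.
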