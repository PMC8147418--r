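---
title: "Methods: chromosome-arm aneuploidy scores and tissue identity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromosome-arm aneuploidy scores and tissue identity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aneuarm)
```

## The scientific question

Cancer genomes recurrently gain and lose whole chromosome arms, and which
arms are gained or lost depends strongly on the tumor's tissue of origin.
`aneuarm` implements a complete analysis connecting three arm-level layers of
data: (i) discrete per-sample arm gain/loss calls in tumors, (ii) mean
arm-wide gene expression in the matching normal tissue (and in the tumors
themselves), and (iii) arm-wide DNA methylation and the chromosomal
distribution of tissue-specific driver genes. The organizing hypothesis is a
dosage logic: arms carrying genes highly expressed in a tissue tend to be
gained in tumors arising from that tissue, lowly expressed arms tend to be
lost, and methylation mirrors expression with opposite sign.

## The arm universe

All analyses run over the 39 autosomal chromosome arms conventionally scored
in arm-level copy-number work: the 44 autosomal arms minus the five
acrocentric short arms (13p, 14p, 15p, 21p, 22p), whose p arms carry
essentially no unique protein-coding genes. Sex chromosomes are excluded.
`arm_definition()` encodes this universe and every feature matrix in the
package has exactly these 39 columns.

## Scores and statistics

**Arm imbalance score.** For a group of samples (all tumors from one tissue
of origin, or one cancer type) and arm $A_i$,
$$\mathrm{score}(A_i, T_j) \;=\; \frac{\#\{\text{samples gaining } A_i\} - \#\{\text{samples losing } A_i\}}{n_{T_j}},$$
a value in $[-1, 1]$. Calls are $-1/0/+1$; entries missing in the input are
re-set to 0, i.e. treated as non-aneuploid, before scoring. Gain and loss
frequencies are reported alongside.

**Arm-level expression features.** Each sample is summarized by 39 features:
the unweighted arithmetic mean RPKM of the genes on each arm. We deliberately
average raw RPKM, not log-transformed values (a `log2p1` flag exists but is
off by default), and per-tissue summaries are grand means over all genes and
all samples of the tissue. Because the gene set of an arm is fixed across
samples, the grand mean equals the mean of per-sample features; the tests
check this identity rather than assuming it.

**Driver imbalance.** Given a table of tissue-specific driver genes labelled
oncogene or tumor suppressor, each arm scores
$\mathrm{frac}_{\mathrm{onco}} - \mathrm{frac}_{\mathrm{TS}}$ among its
resident drivers. Arms with no drivers are *undefined* (`NA`), not 0: a zero
would fabricate a balanced-driver signal where there is no evidence. Undefined
entries are excluded from correlations and mean-imputed (and flagged) only
where clustering needs complete vectors.

**Rank correlations.** All correlation profiles are Spearman correlations:
Pearson on average-ranked data, two-sided p from the $t$ approximation with
$n-2$ degrees of freedom, undefined when fewer than 3 complete pairs remain
or a vector is constant. Profiles are computed both arm-wise (one correlation
per arm, across tissues) and tissue-wise (one per tissue, across arms).

**Positive-count permutation test.** Because individual arm- or tissue-level
correlations have little power, significance is assessed globally: the
observed statistic $P$ is the number of strictly positive correlations along
an axis, and the null is built by shuffling the pairing between the two
matrices — arm labels for the arm-wise axis, group labels for the tissue-wise
axis — recomputing the count $N_i$ in each of $n_{\mathrm{perm}}$ iterations
(1000 by default). The empirical p value is
$\#\{N_i > P\}/n_{\mathrm{perm}}$, with strict inequality. This is the
reported rule; an `add_one` option provides the
$(\#\{N_i \ge P\}+1)/(n_{\mathrm{perm}}+1)$ variant, which is the standard
finite-sample correction and slightly conservative. Undefined correlations
count as non-positive both in $P$ and in every $N_i$, so degenerate columns
cannot inflate significance in either direction.

**Classification.** Tissue of origin is predicted from the 39 features by a
K-nearest-neighbour vote on Euclidean distances with $K=5$ (the best of
$K \in \{3,5,7\}$ for this task), evaluated by leave-one-out
cross-validation and re-checked with stratified 5-fold cross-validation.
Features enter on their raw scale; a `zscore` flag exists for sensitivity
analyses. Neighbour order is made deterministic by sorting on
(distance, sample id), and vote ties go to the class of the nearest tied
neighbour, so results are invariant to row order. The aggregation null asks
whether arms are special: genes are re-partitioned into 39 groups with
exactly the same sizes by permuting the assignment vector, and the LOOCV
accuracy is recomputed per iteration.

**Clustering comparison.** Tissues are clustered hierarchically (complete
linkage on Euclidean distances, both configurable) under four different
39-dimensional descriptions: cancer arm-imbalance scores, mean arm
expression in cancer, mean arm expression in normal tissue, and driver
imbalance. Agreement between two clusterings is the Spearman correlation of
their cophenetic distance matrices over all leaf pairs. The associated p
value inherits the usual independence approximation even though pairs
sharing a leaf are not independent; it should be read as descriptive.

**Methylation.** Illumina 450K beta matrices are accepted post-BMIQ (the
type-I/type-II renormalization is an established upstream method, not part
of this package; the probe type is carried through so upstream processing
can be audited). Probes within 15 bp of a SNP are removed — "within" read
inclusively, so a distance of exactly 15 bp is removed; probes with unknown
distance are retained and counted. Datasets from the same tissue are merged
over their common probes, keeping normal-control samples only. Arm-level
features are unweighted mean betas, aggregated exactly like expression.

## The synthetic cohort generator

Real inputs at consortium scale (pan-cancer call tables, normal-tissue
expression compendia, GEO methylation series) cannot ship with a package, so
`aneuarm` includes a generative model that plants the couplings the analysis
is designed to detect, with known ground truth:

* per tissue $t$ and arm $a$, a log-expression baseline
  $b_{t,a} \sim N(0, \tau^2)$, default $\tau = 0.5$;
* per cancer sample, arm calls with
  $P(\mathrm{gain}) = \mathrm{logit}^{-1}(\alpha + \beta b_{t,a})$ and
  $P(\mathrm{loss}) = \mathrm{logit}^{-1}(\alpha - \beta b_{t,a})$,
  renormalized by their sum when it exceeds 1 (this preserves the
  $b \to -b$ symmetry); defaults $\alpha = -1.5$ (a typical arm is called in
  roughly a third of samples, comparable to pan-cancer arm-call burdens) and
  $\beta = 2$; gains and losses are exclusive per sample-arm, matching the
  $-1/0/+1$ encoding;
* gene expression
  $\mathrm{RPKM} = \exp(\mu_g + b_{t,a} + \lambda c_{s,a} + \varepsilon)$,
  $\varepsilon \sim N(0, \sigma^2)$, with gene baselines
  $\mu_g \sim N(\log 10, 1)$ shared across tissues (an RPKM-like positive
  scale), dosage $\lambda = \log 1.5$ (a single-copy gain on a diploid
  background shifts expression by 3:2) and $\sigma = 0.5$; normal samples
  carry no calls;
* arm-level methylation mean
  $m_{t,a} = \mathrm{logit}^{-1}(\gamma_0 - \gamma_1 b_{t,a})$ with probe
  betas $\sim \mathrm{Beta}(m\kappa, (1-m)\kappa)$; defaults $\gamma_0 = 0$,
  $\gamma_1 = 2$, $\kappa = 50$ (probe-level spread of a few percentage
  points around the arm mean, as seen on the 450K platform);
* driver genes placed, with fidelity $\phi = 0.8$, on arms drawn
  proportionally to the tissue's loss frequency (tumor suppressors) or gain
  frequency (oncogenes), otherwise uniformly.

Default cohort size is 8 tissues with 60 cancer and 60 normal samples each,
20 genes and 15 probes per arm, and 10 methylation samples per tissue —
small enough to regenerate in well under a second, large enough that the
planted couplings dominate sampling noise. All randomness flows through R's
default Mersenne-Twister generator from a single integer seed
(`gen_methylation` and `gen_driver_table` use fixed offsets of that seed so
each is reproducible standalone); identical seeds reproduce cohorts bit for
bit across platforms.

What the generator does *not* emulate: whole-genome doubling (real call sets
are already ploidy-corrected), focal events, subclonality, batch effects,
anatomical substructure within tissues, and correlated gene-gene noise.
Passing tests on synthetic cohorts therefore demonstrate that the statistics
recover planted signal at realistic sizes and reject when there is none —
not that real tissues behave this way.

## Numerical choices

* **Quantile normalization to a reference** (used to put expression and
  imbalance scores on one color scale) uses plotting positions
  $(i - 0.5)/n$ with linear interpolation between reference order
  statistics, clamped at the extremes; tied inputs share the quantile of
  their average rank, so tie structure survives. The quantile dialect is a
  package convention — any standard dialect would serve — chosen for
  determinism and an exact small-sample inverse.
* **Gene-to-arm assignment** anchors a gene at its start coordinate; the
  centromere boundary is the start of the chromosome's first q band
  (coordinates 1-based internally, UCSC 0-based starts converted on read).
  Genes spanning the centromere follow their start. The anchor is a
  convention, not biology: upstream sources rarely state theirs.
* **Stage normalization** maps AJCC strings ("Stage IA" etc.) to their major
  stage, keeps 0 and I as early-stage, and drops samples whose stage is
  missing, since eligibility cannot be verified.
* **Degenerate inputs**: empty groups, arms without genes or probes, and
  non-binary driver roles are hard errors naming the offender; unknown arm
  columns and unannotated probes are dropped with counts; beta values are
  clipped only within 1e-6 of the unit interval, anything worse is an error.
* **Determinism**: permutations are drawn with R's `sample.int` from one
  seeded stream per test invocation; KNN tie-breaks are lexicographic; rows
  are sorted by id before clustering so dendrograms do not depend on input
  order.

## Worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(mode = "synthetic", n_perm = 1000,
                       n_perm_shuffle = 100, seed = 1)
res <- run_pipeline(cfg, out_dir = "aneuarm_run")
str(res$summary)
```

On the default cohort this reports all-positive arm-wise and tissue-wise
expression-imbalance correlations with permutation p = 0, LOOCV and 5-fold
KNN accuracy of 1.0 with a gene-aggregation shuffle p of 0, tissue-wise
methylation-expression correlations that are all negative, and cophenetic
agreement that is high between the imbalance- and expression-based
clusterings but weak against the driver-based clustering. The same numbers
are recomputed from scratch by `scripts/acceptance.R`.

## Problem sizes used in the test-suite

The suite validates the estimators at the generator's default study
conditions (8 tissues x 60 samples), with 20 seeded replicates for recovery
checks, 500 null dataset pairs for calibration of the permutation test
(empirical rejection at the 0.05 level must land in [0.03, 0.07]), 100
random instances against the brute-force imbalance oracle, and 200 random
feature matrices for the ultrametricity property. These sizes give stable
Monte-Carlo estimates while keeping a full run around half a minute.

## Known limitations

* The strict-inequality empirical p has a resolution of
  $1/n_{\mathrm{perm}}$ and can be exactly 0; the `add_one` variant never is.
* Whether the original analyses standardized features before KNN, counted
  undefined correlations as positive, or read "within 15 bp" inclusively is
  not documented anywhere we could verify; our choices (raw scale,
  non-positive, inclusive) are stated here and in the function
  documentation rather than silently assumed.
* Cophenetic-correlation p values treat leaf pairs as independent; they are
  not.
* Arm-level aggregation deliberately ignores within-arm structure (focal
  amplifications, gene-level dosage compensation); the package is not a tool
  for focal copy-number analysis.
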