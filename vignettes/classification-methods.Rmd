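---
title: "Classifying tissue specificity from expression atlases: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying tissue specificity from expression atlases: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tissuespec)
```

## The classification model

Bulk RNA-seq atlases such as the Human Protein Atlas (HPA) and GTEx profile
every protein-coding gene across a few dozen tissues. `tissuespec` assigns
each gene to exactly one of six expression-specificity categories from its
gene × tissue FPKM vector, given two constants: a **detection cutoff**
(`cutoff`, default 0.5 FPKM) below which a gene is treated as absent from a
tissue, and an **enrichment fold** (`fold`, default 5).

Writing $x_1, \dots, x_n$ for a gene's per-tissue levels, the rules are
evaluated in precedence order, first match wins:

1. **Not detected** — $x_t < c$ for every tissue $t$.
2. **Tissue enriched** — some tissue has $x_t \ge c$ and
   $x_t \ge f \cdot \max_{s \ne t} x_s$.
3. **Group enriched** — for some group size $k \in \{k_{\min}, \dots,
   k_{\max}\}$ (defaults 2–7), the $k$ highest tissues are all detected and
   their mean is $\ge f$ times the highest tissue outside the group; the
   smallest such $k$ is reported.
4. **Tissue enhanced** — some detected tissue has
   $x_t \ge f \cdot \bar{x}$, the mean over *all* tissues including $t$;
   every such tissue is reported as elevated.
5. **Expressed in all** — $x_t \ge c$ everywhere.
6. **Mixed** — detected somewhere but matching nothing above.

The first three categories together are called **elevated**. The precedence
order is what makes the six classes a partition: "mixed" is explicitly the
remainder, and a profile that satisfies both the enriched and enhanced
inequalities is counted once, as enriched.

Three deliberate readings of the rules deserve a note:

* **Inclusive comparisons.** All thresholds use $\ge$ ("at least
  fold-fold"), so a tissue at exactly $f$ times its reference is elevated.
* **Multiplicative form.** Comparisons are computed as
  $x \ge f \cdot m$, never as $x / m \ge f$, so a reference of zero (a gene
  seen in a single tissue only) is handled without special cases. The
  *reported* `fold_score` does divide, guarding the denominator from below
  at $c / f$.
* **Detected elevation.** The elevated tissue(s) must themselves be at or
  above the cutoff — an "enriched" call in a tissue where the gene is not
  even detected would be contradictory. Likewise, the enhanced reference
  mean includes the candidate tissue itself, the literal reading of
  "average levels in all tissues".

Genes detected in exactly one tissue that fail every fold rule are assigned
`mixed` even though that label classically implies detection in at least two
tissues; leaving them uncategorised would break the partition. Their
`n_detected = 1` flags them in the output.

### Why the top-k search suffices for groups

The group rule quantifies over all tissue subsets of sizes
$k_{\min}..k_{\max}$, which is exponential if taken literally. The
classifier only examines the $k$ highest tissues for each $k$
(ties broken lexicographically by tissue label): for any other size-$k$
subset $S$, the excluded-maximum is at least the $(k{+}1)$-th order
statistic, and the mean of $S$ is at most the mean of the top $k$, so the
top-$k$ group dominates $S$ on both sides of the inequality; if the rule
cannot be satisfied by the top-$k$ tissues it cannot be satisfied at all.
The test suite proves this equivalence empirically against exhaustive
subset enumeration on a thousand randomised profiles of up to ten tissues.

## From samples to tissues

Atlases carry several biological replicates per tissue. The classifier
consumes tissue-level values; `aggregate_to_tissue()` collapses replicates
by the **arithmetic mean** of FPKM. The mean preserves linearity with the
fold rules and is the conventional atlas summary; a median would be more
robust to a single outlier replicate but changes the boundary behaviour of
every fold rule, and nothing in the source material indicates it was used.
Tissue columns are ordered lexicographically so every downstream file is
byte-deterministic. Missing values are rejected rather than imputed: atlas
matrices are dense by construction, and a hole indicates an upstream
problem the user should see, not paper over.

## Cross-atlas concordance

Two atlases classified independently can be compared on their shared gene
universe (`compare_classifications()`): a 6 × 6 category cross-tabulation, the
overlap of "expressed in all" calls with the other atlas's category
breakdown of the discordant genes, and per-tissue agreement of elevated
calls. Tissue vocabularies rarely match one-to-one (one atlas's single
"brain" against another's cerebellum/cortex/pituitary), so agreement is
computed under a user-supplied many-to-many tissue mapping.

The per-tissue rule follows the figure-legend convention of the atlas
literature: a gene tissue-enriched in dataset A counts as *supported*
("both") when dataset B places it in **any elevated category** in at least
one mapped partner tissue. A stricter enriched-vs-enriched mode
(`mode = "enriched"`) is provided, because the looser reading is a
convention, not a law; the default follows the published wording. Genes
absent from either dataset are excluded entirely (intersection semantics) —
concordance is only meaningful on a common universe.

## Interindividual variation

For tissues with enough biological replicates, `gene_cv()` computes each
detected gene's coefficient of variation across replicates
(CV = sd/mean, sample standard deviation with $n-1$), and
`cv_shift_test()` asks whether genes classified "expressed in all" have
systematically lower CVs than the rest — the housekeeping-stability
hypothesis. Choices made here:

* CV is computed on FPKM, not log-FPKM, and only for genes whose replicate
  mean clears the detection cutoff: the ratio sd/mean explodes as the mean
  approaches zero, and sub-cutoff genes are not meaningfully expressed in
  the tissue.
* The shift test is a **two-sided Mann–Whitney U** (normal approximation
  with tie correction). CV distributions are heavily right-skewed, so a
  rank test is the standard choice; the direction of the shift is reported
  separately as a median comparison.
* `min_replicates` defaults to 3, the minimum for a non-trivial sample
  standard deviation; the analysis is only as good as the replicate count,
  which is why published analyses restrict it to the deeply replicated
  tissues.

## The synthetic atlas generator

`generate_atlas()` produces a replicate-level FPKM matrix with known
("planted") per-gene categories so the entire pipeline can be exercised and
validated without external downloads. Per gene, a tissue-level mean vector
is constructed for its planted category, then replicates are drawn as
`mean × LogNormal(0, σ)` with σ set so the replicate CV equals the spec's
noise level — 0.1 for expressed-in-all genes and 0.4 for everything else by
default, planting the dispersion contrast the CV analysis looks for.

Default dimensions follow the atlas setting the package mirrors: 32
tissues, 8 replicates per tissue (a typical "well-replicated tissue" depth,
and enough for stable per-gene CVs), 2,000 genes (large enough for stable
category fractions, small enough to keep test runs in seconds), and
category proportions equal to the published six-way breakdown of the
18,684 protein-coding genes. The planted fold separation is 10, double
the classifier's threshold of 5, so moderate replicate noise does not push
planted calls across rule boundaries.

The constructions are exact at the tissue-mean level — each vector
provably satisfies its own category rule and violates every
higher-precedence rule:

* **not_detected** — all tissues uniform on $(0, u)$ with
  $u$ = `sub_cutoff_ceiling` (default `cutoff/2`).
* **expressed_in_all** — a common log-normal baseline (clamped to the
  cutoff) times per-tissue factors in $[1, 2)$: with max/min < 2 < fold no
  enrichment rule can fire.
* **tissue_enriched** — a detected runner-up tissue pins the off-target
  maximum; the target sits at `planted_fold` times it.
* **group_enriched** — a random group of size 2–7 within 1.2× of its
  baseline; the best outsider is placed at exactly `group mean /
  planted_fold`, so the group rule holds with margin while no smaller
  subgroup can qualify.
* **enhanced** — the one genuinely constrained pattern: one high tissue,
  `group_max + 1` moderate tissues (one more than any group window can
  absorb), the rest sub-cutoff. The high tissue is set to `planted_fold ×`
  the all-tissue mean and must still stay below `fold ×` the moderate
  level; that is only satisfiable when the tissue panel is large relative
  to `planted_fold` (for the defaults, at least 27 tissues). The moderate
  level is floored accordingly.
* **mixed** — detected tissues in $[1, 1.9] \times$ cutoff and off tissues
  in $[0.8, 1] \times$ `sub_cutoff_ceiling`, keeping the detected set
  within a factor 1.9 (no enrichment), the off tissues close enough that no
  small detected set is fivefold above them, and the overall mean high
  enough that the enhanced rule fails too.

Because some of these patterns are infeasible for small tissue panels or
extreme parameter choices, `synthetic_spec()` validates the controlling
inequalities up front and **errors rather than silently planting a wrong
label**. Truth is defined before noise: the recovery report exposes, rather
than hides, boundary crossings caused by replicate noise (at default noise
the crossing rate is a fraction of a percent, essentially all at the
detected/undetected boundary of genes whose lowest tissue sits near the
cutoff).

Randomness is reproducible and order-independent: each gene draws from its
own substream derived from the seed and the gene index, so generating 20 or
2,000 genes yields identical values for the genes they share. A separate
`structure_seed` lets two atlases share planted truth while drawing
independent noise — the "two noisy replicates of one truth" scenario used
in the concordance tests.

### What the generator does and does not emulate

It emulates the data *structure* the classifier consumes: planted category
fractions, fold separations, multiplicative replicate noise, and the lower
interindividual dispersion of ubiquitously expressed genes. It does not
emulate read-level realism — no count sampling or library-size effects, no
batch effects, no correlated co-expression modules, and its category
geometry is cleaner than real atlases, where genes sit *on* rule
boundaries. Passing recovery tests therefore demonstrate correctness of
the pipeline's logic, not expected accuracy on real data, where category
assignments near the cutoff are intrinsically unstable (the published
atlases themselves disagree on several hundred "expressed in all" genes,
mostly reclassified as "mixed" by the other dataset).

## Numerical and interface choices

* Ties in the descending tissue sort are broken lexicographically by label;
  with tied values the classification itself is unaffected (the rules
  compare values, not ranks) but the reported group membership is
  deterministic.
* `group_max` is capped at `n_tissues - 1` at classification time, since a
  group must leave at least one tissue outside.
* The matrix writer emits `%.17g` so write→read round trips are bit-exact;
  report tables use fixed 4-decimal formatting for readability instead.
* Report files are TSV with lexicographic row orders throughout;
  re-running any stage on the same inputs reproduces identical bytes.

## Problem sizes used by the test suite

The suite validates the classifier against brute-force enumeration on
1,000 random profiles of 4–10 tissues; recovery, monotonicity and
concordance properties on planted atlases of 300–2,000 genes × 16–32
tissues; and the null calibration of the CV test on 400 simulated tissues
(25 atlases × 16 tissues at 250 genes, 6 replicates, equal dispersions),
where the two-sided rejection rate at α = 0.05 is required to stay within
0.03–0.07. These sizes give stable verdicts in under a minute each.

## Known limitations

* FPKM is taken as given; no normalisation (TPM conversion, quantile) is
  performed, and comparing atlases normalised differently is the user's
  responsibility.
* The classifier is threshold-based by design — it reproduces a published
  categorical scheme rather than a continuous specificity index (e.g. tau),
  and small perturbations can move genes between adjacent categories.
* Concordance semantics depend on the tissue mapping supplied; a poor
  mapping shows up as inflated "only" counts, not as an error.
* The CV analysis assumes replicates are exchangeable individuals; it does
  not model donor covariates or postmortem-interval effects.
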