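---
title: "Methods: tetranucleotide stability diagrams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tetranucleotide stability diagrams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetraphase)
```

This vignette is the package's account of its own methods: the model
behind each stage, the tunable parameters and their defaults, the
numerical choices, what the synthetic-data generator does and does not
emulate, and the known limitations.

## Canonical tetranucleotide features

A double-stranded genome contributes every 4-mer and its reverse
complement in equal measure, so the 256 raw tetranucleotides carry only
136 distinguishable frequencies: 16 palindromic 4-mers plus 120
complement pairs, each represented by the lexicographic minimum of the
pair. `build_canonical_index()` constructs this partition by exhaustive
enumeration; `count_tetramers()` slides a width-4, step-1 window over
each read, skips windows containing anything outside A/C/G/T, and counts
single-strand only — the canonical collapse makes scanning the reverse
strand redundant, and the test suite asserts the resulting strand
invariance property directly.

The feature vector appends to the 136 frequencies one ratio per
*unordered* class pair, numerator the lexicographically earlier class:
136 + C(136,2) = 9,316 features. Ordered ratios would double the ratio
count while adding only reciprocals, which carry no extra discriminative
information for a linear method; the unordered convention keeps the
feature count at the canonical 9,316.

Two conventions worth noting:

* **Frequencies are fractions** (summing to 1), not percentages. Ratios
  are scale-invariant and the discriminant projection is equivariant to a
  uniform feature rescaling, so this choice is cosmetic; a test pins the
  invariance.
* **Zero counts.** Real metagenomes at sequencing scale contain every
  tetranucleotide, but desk-scale synthetic inputs may not, and a zero
  frequency makes its ratios undefined. The default
  `pseudocount_policy = "add_one"` adds 1 to *every* class count whenever
  any class is empty (announced via a message), preserving relative
  ordering while keeping all ratios finite; `"error"` refuses instead.
  At realistic depths the policy never triggers.

## Discriminant ordination

`fit_lda()` maximizes between-class relative to within-class scatter and
returns the top two discriminant axes as diagram coordinates. With 9,316
features and typically far fewer samples, the within-class scatter
$S_W$ is singular, so the solver:

1. centres the feature matrix and reduces it by thin SVD to the span of
   the data (rank ≤ n − 1), which loses nothing — discriminant directions
   with no data support are unidentifiable;
2. adds a ridge $\epsilon I$ to $S_W$ in the reduced space, with
   $\epsilon$ = `shrink` × mean diagonal of $S_W$ (default
   `shrink = 1e-3`; the unit test that compares against a dense
   generalized-eigen oracle uses `1e-9` to emulate the unregularized
   solution on a well-posed small problem);
3. solves $S_B w = \lambda (S_W + \epsilon I) w$ by Cholesky reduction to
   a symmetric eigenproblem.

Axes are scaled so the discriminant space is within-class whitened
(matching the common LDA scaling convention) and signs are fixed so the
lexicographically first class has nonnegative mean on every axis — signs
are otherwise arbitrary and fixing them makes coordinates reproducible
across platforms. With two classes there is a single discriminant axis
and the y-coordinate is zero.

Classification (used by `evaluate_split()`) is nearest class centroid in
the whitened discriminant space adjusted by log priors proportional to
training class sizes — the Gaussian LDA rule restricted to the
discriminant subspace. `evaluate_split()` stratifies the split per class
(default 80% train, seeded), and reports accuracy plus class-weighted
precision and F1: the label sets this method serves are heavily
imbalanced, and support-weighted averaging is the conventional default
when a single number per metric is wanted. The model reported by
`fit_lda()` is fit on all samples; the held-out split exists to measure
generalization, not to produce the published coordinates.

## KNN phase mapping

`build_phase_grid()` lays a `resolution × resolution` grid (default
200 × 200) over the coordinate bounding box expanded by 5% per side and
labels each cell centre by majority vote among the k nearest metagenomes
in Euclidean coordinate distance, with uniform votes. Ties are certain at
even k, so the tie-break is fully specified: most votes, then smallest
summed distance to the tied classes' voters, then lexicographically
smallest group key. `classify_point()` applies the identical rule to
arbitrary queries (the test suite checks it against an exhaustive
distance-sort oracle), and `assign_phases()` classifies each metagenome
at its own coordinates — not its containing cell — to measure phase
concordance.

**Choosing k.** The default k = 500 is calibrated for collections of
10,000+ metagenomes, where it is roughly 4% of the data and smooths out
boundary noise that smaller k over-fits. k clamps to the sample count, but
at desk scale a clamped k degenerates: with 200 samples, k = 200 votes
every query to the global plurality class. The package's desk-scale runs
therefore use k ≈ 10% of n (k = 20 for the standard 5 × 40 cohort), which
preserves the local-neighbourhood character of the vote; choose k in that
spirit for intermediate collections.

## Gene abundance overlays and statistics

`parse_gff3_annotations()` counts identifier occurrences in the
IMG-style attribute keys `cog`, `ko`, `pfam`, `ec_number` (configurable,
since GFF3 attribute conventions vary by annotation pipeline version);
a feature line carrying several namespaces increments each, and
comma-separated multi-valued attributes count one per value.
`build_abundance_table()` normalizes to counts per 10⁹ assembled bases.
Three missing-data rules are deliberate:

* no annotation file → the sample's whole row is **missing** (`NA`),
  never zero — hiding, not claiming absence;
* an annotated sample lacking an identifier → **zero**, a true absence
  among counted features;
* statistics drop missing values listwise per gene.

Group comparisons use Welch's heteroscedastic ANOVA
(`stats::oneway.test`) and Games-Howell post hoc pairs: for groups $i,j$,
$t = |m_i - m_j| / \sqrt{s_i^2/n_i + s_j^2/n_j}$ with Welch–Satterthwaite
degrees of freedom, referred to the studentized-range distribution as
$q = t\sqrt{2}$ with the total group count (`stats::ptukey`, computed
numerically; agreement with an independent reference implementation is
asserted to 1e-6 in the tests, and the two-group Welch F equals the
squared Welch t to 1e-9). Significance tags use ≤ thresholds:
`*` ≤ 0.05, `**` ≤ 0.01, `***` ≤ 0.001. No multiple-testing correction is
applied across genes — the statistics are per-gene figure annotations,
not a genome-wide screen.

`overlay_values()` maps abundance linearly onto [0, 1] colormap positions
(reversed cividis in `render_diagram()`), clips at the range ends, hides
missing values, and accepts a `midpoint` that is rescaled to colour
position 0.5 — a piecewise-linear "heat" adjustment for genes whose
counts are skewed.

## Importance ranking

`rank_importances()` trains a ranger random forest (500 trees,
sqrt-features, unlimited depth, seeded, single-threaded for
reproducibility) on a stratified 75%/25% split and reports mean decrease
in impurity, normalized to sum to 1, with held-out accuracy alongside.
`per_class_rankings()` fits one-vs-rest forests, one per ecosystem,
because a per-ecosystem list needs a per-ecosystem score; each entry is
tagged `abundance` when the group's mean (on the same zero-imputed values
the model sees) exceeds the complement's mean, else `sparsity`. Missing
abundances are imputed as zero *for the model input only* — missingness
tracks annotation-pipeline availability, not biology, and the returned
tables never overwrite the input. Exact importance ties order
lexicographically by gene id.

## The synthetic-data generator

`make_ecosystem_models()` gives each ecosystem an order-3 Markov chain
over A/C/G/T. This device is chosen to match the feature space: 4-mer
frequencies are exactly the sufficient statistics of an order-3 chain, so
the generator controls precisely what the pipeline measures, and the
stationary canonical 4-mer distribution is computable in closed form
(`stationary_tetramer_freqs()`, via the 64-state trimer chain) — an
analytic oracle the tests compare empirical counts against. All groups
share a base transition table (logit-scale Gaussian, sd 0.5 — enough
heterogeneity across contexts that no transition is near-deterministic);
each group adds independent logit noise of sd `separation` and
renormalizes, so `separation = 0` gives exchangeable groups and
divergence grows monotonically with it.

The standard study conditions are 5 groups × 40 metagenomes, 300 reads ×
150 bp per metagenome, `separation = 0.8` — sizes at which a full
pipeline run takes seconds, per-sample sampling noise is visible but
small against a separation-0.8 signal, and the 9,316-feature p ≫ n regime
is genuinely exercised. Gene counts are negative-binomial (size 2, base
mean 20) rather than Poisson so the unequal-variance statistics pathway is
stressed with realistic overdispersion; `assembled_bases` defaults to
`reads_per_sample × read_length`.

What the generator does **not** emulate: read errors and quality scores,
within-group taxonomic structure (all samples of a group share one chain;
real ecosystems vary internally), genome-scale repeat structure, GC
covariates, or uneven sequencing depth. Passing tests therefore show the
pipeline recovers structure *that is present in the stated form*, not
that real ecosystems are this separable — on real data the held-out
metrics will be lower and phase boundaries fuzzier.

## Numerical choices and degenerate inputs

* SVD rank cut-off: singular values below 1e-9 × the largest are
  discarded.
* Frequencies sum to 1 within 1e-12 by construction; feature-vector
  ratio consistency is asserted to 1e-12.
* Welch/Games-Howell require every group to have n ≥ 2 and nonzero
  variance; degenerate groups are named in the error.
* `to_frequencies()` errors on an all-invalid (zero-window) profile.
* A degenerate (zero-width) coordinate axis pads the grid symmetrically
  rather than collapsing.
* Empty sequence files yield empty streams; empty annotation lists yield
  a 0-column abundance table.

## Limitations

* k = 4 only in the public surface; no alternative k-mer sizes.
* Two discriminant axes only; no unsupervised ordinations.
* KNN is exact brute force — correct and adequate to a few thousand
  points, but no spatial index for very large grids.
* The Games-Howell p-value relies on `ptukey`, which is itself a
  numerical quadrature; agreement with an independent implementation is
  ~1e-8 in practice, asserted at 1e-6.
* Per-ecosystem importances come from one-vs-rest forests; a single
  multiclass forest would give different (global) importances.
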