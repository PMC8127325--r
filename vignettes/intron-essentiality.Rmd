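---
title: "Intron structure and gene essentiality: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intron structure and gene essentiality: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`IntronEss` studies whether the introns of essential genes carry
characteristic structure — in length, count, base composition and splice
dialect — and whether that structure is strong enough to predict gene
essentiality from intronic sequence alone. This vignette documents the
models, the tunable parameters, the synthetic data the package validates
itself on, and the design decisions taken where more than one reasonable
choice existed.

## The data model

A **gene record** carries a gene id, strand, an essentiality label, and an
ordered table of introns. Introns are stored strand-corrected 5'→3', with
`ordinal` 1 marking the transcript's first intron. Extraction from
FASTA + GFF3 picks, per gene, the transcript with the greatest total CDS
length (ties broken by lexicographically smallest transcript id), and introns
are the gaps between that transcript's consecutive exons. We use the
longest-CDS rule, which recent annotation practice favours as the most
biologically representative isoform choice; a longest-transcript variant
behaves very similarly and is not implemented.

Essentiality labels come from an OGEE-style table of study counts. Genes
whose studies all agree are essential or nonessential outright. For
*conditional* genes (studies disagree), the binary task groups them with
essential genes when at least half the studies called them essential and
discards them otherwise. At exactly one half the gene is kept as essential:
the discard rule is stated as "fewer than half", so the boundary case
survives it. `assign_label(half_is_essential = FALSE)` flips this if a
stricter reading is wanted. The three-way category is retained for all
feature analyses.

Internally, interval arithmetic follows the host conventions of the I/O
libraries (1-based inclusive, as in GFF3 and IRanges); all conversions
happen inside the readers and writers.

## Intron features

* **GC-motif density** — occurrences of the dinucleotide `GC`, counted at
  every start position by exhaustive scan, divided by intron length (per
  bp). The motif is configurable; overlapping occurrences of the default
  two-letter motif are impossible, so the density is bounded by 0.5.
* **GC content excluding motifs** — `(#G + #C − 2·n_GC)/L`, the GC fraction
  left after removing the bases consumed by motif occurrences. The identity
  `gc_content = gc_content_excl_motifs + 2·gc_motif_density` holds exactly
  and is asserted in the tests.
* **Splice dialect** — an intron is flagged unusual at the 5' end when it
  does not begin with `GT`, and at the 3' end when it does not end with
  `AG` (the canonical spliceosomal boundaries; minor intron classes differ).
  Ambiguity codes at a boundary count as unusual: a conservative,
  deterministic rule.
* **CpG islands** — the Takai–Jones sliding-window criteria: a 200-bp
  window qualifies at GC ≥ 0.55 and observed/expected CpG ≥ 0.65 (expected
  = #C·#G/window); runs of qualifying windows are merged when closer than
  100 bp, trimmed one base at a time (alternating 5'/3') until the whole
  interval qualifies, and reported at length ≥ 500 bp. These parameter
  values follow the published island definition and are all configurable
  through `cpg_criteria()`. Sequences shorter than the window return no
  islands rather than an error.
* **Ambiguity codes** are kept in sequences, excluded from GC numerators,
  counted in lengths, and never match motifs.

The per-gene feature vector has seven entries: average intron size, intron
count, total intronic bp, GC-motif density of the first intron and the
unweighted mean over later introns, and motif-free GC count for first and
later introns likewise. Group-level GC densities are unweighted means of
per-intron densities, not pooled base counts — matching a per-intron
box-plot presentation; the first/later *ratios* are invariant to that
choice and to the per-bp/per-kb unit choice. Later-intron entries are
undefined for single-intron genes and flagged missing rather than dropped.

## The convolutional intron classifier

The sequence model scores a fixed-length intron window
`s` as `f(s) = net(pool(rect(conv(s))))`:

1. `conv` — `n_filters` filters of width `window` slide over the L×4
   one-hot matrix (columns A, C, G, T; N/ambiguity/padding rows are uniform
   0.25 so they are uninformative).
2. `rect` — a rectifier (ReLU by default; ELU available in the grid).
3. `pool` — **average** pooling across sequence positions, one value per
   filter, measuring the cumulative presence of each filter's motif.
4. `net` — a fully connected layer (`fc_units`) with rectifier and dropout,
   then a two-unit softmax giving the essential/nonessential probabilities.

Defaults mirror the selected reference architecture: 128 filters of width
24, 128 fully connected units, dropout 0.2, L2 10⁻⁶, 30 epochs, batch 64.
L1 regularisation is supported and defaults to 0. The optimiser is Adam at
the conventional learning rate of 10⁻³. Training is deterministic given
the config seed, up to BLAS summation order.

Two models are trained per corpus: one on the **first 1,000 bp** and one on
the **last 1,000 bp** of every intron (window length configurable).
Introns shorter than the window are padded with uniform rows (first windows
right-padded, last windows left-padded), following the DeepBind-style
encoding convention the model derives from; the padding length is recorded
so short introns can be excluded in sensitivity analyses.

**Splits and balance.** All introns of a gene share one partition (test, or
one of three cross-validation folds), stratified by binary label — this is
what makes test AUC meaningful, and leakage is asserted to be exactly zero
in the tests. Each training epoch draws equal counts from both classes
(minority oversampled with replacement), interleaved so every batch is
50/50 within one example. Validation AUC is computed on the full validation
fold: AUC is invariant to class resampling, so balancing the validation set
would not change the recorded metric.

**Grid search.** The hyperparameter grid spans the four searched axes —
dropout {0, 0.2, 0.5} × window {16, 24} × activation {ReLU, ELU} × L2
{10⁻⁴, 10⁻⁶, 0} — exactly 36 candidate models, scored by mean validation
AUC over the three folds. The grid values were chosen to bracket the
reference combination (dropout 0.2, window 24, ReLU, L2 10⁻⁶) while
keeping the search auditable. Ties break toward smaller L2, then smaller
dropout (less regularisation only when it is free).

## Gene-level scoring

A gene's **majority** score is the arithmetic mean of its introns' scores
under one model. The **double** classifier pools the intron scores from
the first- and last-window models; because both models score the same
introns, this equals the average of the two majority scores. For
first-intron-only evaluation, the **dual average** is the mean of the two
models' scores on that single intron. ROC curves sweep thresholds over the
unique scores with ties grouped — equivalent to half-credit in the
Mann–Whitney formulation, which the tests verify by exhaustive pair
counting — and AUC is the trapezoidal area.

## The seven-feature network

Feature vectors are z-scored with statistics learned on training genes
only; constant features map to zero, and missing later-intron entries are
imputed with the training median plus an appended missingness indicator
(imputation keeps single-intron genes in the corpus rather than dropping
them). The classifier is a fully
connected softmax network whose depth/width/dropout/L2 are grid-searched
(depth {1, 2} × width {32, 128} × dropout {0, 0.2} × L2 {0, 10⁻⁴}) by
threefold cross-validated AUC. The final predictor is a 10-model ensemble
that reduces variance and generalisation error; members differ by
initialisation seed and a bootstrap resample of the training genes
(this package's mechanism for member diversity), and the tests verify the
variance reduction empirically. The ensemble score is the unweighted mean
of member scores.

## The synthetic corpus

The generator is the package's test bed: it plants, per class
(essential / conditional / nonessential), the effect structure the analysis
measures, with defaults frozen to the study conditions:

| parameter | essential | conditional | nonessential |
|---|---|---|---|
| genes per class (scale 1) | 100 | 100 | 100 |
| mean intron count | 7 | 6 | 5 |
| mean first-intron length (bp) | 2,000 | 4,000 | 6,600 |
| mean later-intron length (bp) | 900 | 1,100 | 1,300 |
| GC-motif density first / later | 0.0810 / 0.0600 | 0.0732 / 0.0600 | 0.0678 / 0.0600 |
| P(unusual 5') / P(unusual 3') | 0.02 / 0.015 | 0.045 / 0.03 | 0.08 / 0.05 |
| motif, rate per bp | `TTACGTAACGGTTACG`, 0.004 | `AGGTTCAAGGTTCAAG`, 0.004 | `AATGGATTGAATCCAT`, 0.004 |

The constrained quantities are the ratios and orderings: first-intron mean
length ratio nonessential/essential = 3.3; GC-density first/later ratios
1.35, 1.22, 1.13; intron counts ordered essential > conditional >
nonessential; unusual-splice probabilities ordered essential < conditional
< nonessential. Absolute lengths, the 0.42 background GC, and the shared
later-intron density are generator choices (only the ratios are
constrained), sized to resemble human intron scales while keeping desk-scale
corpora tractable. `validate_corpus_config()` enforces every invariant and
names violations.

Design notes:

* **Length law** — log-normal (right-skewed, strictly positive, median
  below mean as in notched-box presentations of intron lengths), with
  `len_dispersion` the sdlog (default 0.75) and a 70-bp floor (about the
  minimum length of a spliceable human intron).
* **Intron counts** — shifted Poisson (1 + Poisson(mean−1)), so every gene
  has at least one intron; intronless genes carry no information for an
  intron-based analysis.
* **GC-density calibration** — sequences are iid background at the class
  GC composition; `GC` dinucleotides are planted in disjoint interior
  3-bp slots at a count solved from
  E[#GC] = k + q·(L−5−3k+k/S), q = (base_gc/2)², with randomised rounding
  of k, so the expected measured density equals the target exactly for
  canonical boundaries without motif insertion. The tests verify the
  realised mean within two standard errors over 10,000 introns. Motif
  insertion dilutes the realised density by a few percent — identically in
  first and later introns, so the target ratios are unaffected.
* **Discriminative motifs** — each class carries its own 16-mer, chosen
  free of the `GC` dinucleotide so motif planting cannot perturb the
  density targets. The default rate of 0.004 copies/bp puts about two
  copies in a 500-bp window (the reduced design point used in the tests),
  so the intron-level classifier has learnable per-window signal; at much
  lower rates many windows carry no copy and intron-level separability is
  capped regardless of classifier quality.
* **Conditional study fractions** are uniform on {0.1, …, 0.9}, so the
  ≥ 50 % grouping rule genuinely splits the class.
* **CpG islands are not separately planted**: island presence emerges from
  the GC parameters, and the report states whatever the corpus yields.
* **Emission** embeds introns between 150-bp generated exons on synthetic
  contigs (random strand per gene; minus-strand genes written
  reverse-complemented), with CDS features equal to exons so the
  longest-CDS rule is exercised; re-extraction is exact by construction
  and asserted in the tests.

What the generator does **not** emulate: real human base composition and
repeat content, transcript isoform diversity, chromatin-linked intron
position effects, or any correlation structure between features beyond the
planted class means. Passing tests therefore demonstrate that the pipeline
recovers what was planted — not that the biological effect sizes would be
recovered from real genomes.

## Statistics

Group comparisons use the Mann–Whitney rank test: exact two-sided p by full
enumeration of label assignments for n₁+n₂ ≤ 12 (valid under ties), and the
tie-corrected normal approximation otherwise — the standard companion to
notched-box summaries of skewed length data. Notches are the
Gaussian-asymptotic
median ± 1.57·IQR/√n. Raw p-values are reported without multiple-testing
correction, matching the figure-style presentation; a Benjamini–Hochberg
option is available via `stats::p.adjust` on the report's test table.

## Numerical choices and degenerate inputs

* Softmax is computed with row-max subtraction; cross-entropy clamps
  probabilities at 10⁻¹²; non-finite training loss aborts with a
  diagnostic rather than continuing silently.
* Zero-weight networks output exactly (0.5, 0.5); zero-epoch training is a
  no-op; batch scoring equals one-by-one scoring.
* Empty sequences error in every feature; sequences shorter than four
  bases error in splice classification; sequences shorter than the CpG
  window return no islands.
* Constant features normalise to zero rather than NaN.
* Every stochastic component (corpus, splits, batches, initialisation,
  dropout, bootstrap) is seeded, and seed handling never clobbers the
  caller's RNG stream.

## Problem sizes used in validation

The test suite validates parameter recovery on a corpus of 2,000 genes per
class (about 36,000 introns, ~57 Mb of sequence) through the full
emit/extract/feature path, and classifier behaviour on a reduced design
point — 600 genes, 500-bp windows, 32 filters, 10 epochs — where the
planted-motif corpus yields intron-level test AUC above 0.8, gene-level
majority AUC above the intron-level AUC, and near-chance AUC under permuted
labels. These sizes were chosen as the smallest at which the planted
effects dominate sampling noise; the full-scale architecture (1,000-bp
windows, 128 filters, 30 epochs) is the package default for real use.

## Known limitations

* The CNN is plain R matrix algebra: fast enough for desk-scale corpora,
  not for full-genome training runs.
* The double classifier's advantage over the majority classifiers is a
  small, stochastic effect; it is asserted at a fixed seed and described
  as such.
* Real-data adapters (Ensembl/OGEE download) are out of scope, so the
  original human corpus counts and AUCs are not reproduced here.
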