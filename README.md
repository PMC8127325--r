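# IntronEss

Tools for studying how intron structure relates to gene essentiality, and
for predicting essentiality from intronic sequence alone.

Essential genes — those whose single knockout is lethal or severely reduces
fitness — sit at the hubs of protein-interaction networks and are under
strong pressure to keep their expression timing and transcript structure
stable. Intron loss and deletion, which occur preferentially in long introns
and at the 3' end of genes, threaten exactly that stability. `IntronEss`
implements the full computational workflow for asking whether introns of
essential genes look different from those of nonessential genes, and whether
a classifier can read essentiality off intron sequence:

- **Extraction** — genome FASTA + GFF3 in, one transcript per gene (the one
  with the longest total CDS), introns as exon gaps, strand-corrected
  5'→3', labeled from an OGEE-style study-count table (conditional genes
  are grouped with essential genes when ≥ 50 % of studies agree, discarded
  otherwise).
- **Intron features** — GC-motif density (overlapping `GC` dinucleotide
  occurrences per bp), GC content with motif content subtracted, unusual
  5'/3' splice boundaries (anything other than `GT…AG`), Takai–Jones CpG
  islands (200-bp window, GC ≥ 0.55, obs/exp CpG ≥ 0.65, length ≥ 500), and
  the seven-entry per-gene feature vector (average intron size, intron
  count, total intronic bp, first/later GC density, first/later motif-free
  GC count).
- **Sequence classifier** — a convolutional network
  `f(s) = net(pool(rect(conv(s))))` over one-hot encoded first/last 1,000-bp
  intron windows: motif-detecting filters, rectifier, average pooling across
  positions, fully connected softmax head; trained with Adam, cross-entropy,
  class-balanced batches, gene-grouped train/validation/test splits, and a
  36-model grid search (dropout × window × activation × L2) by threefold
  cross-validated AUC. Implemented natively in R matrix algebra.
- **Gene scoring** — majority classifier (mean of a gene's intron scores),
  double majority classifier (pooled over both window models), first-intron
  dual averages, ROC/AUC evaluation.
- **Feature model** — z-score normalisation learned on training genes, a
  grid-searched fully connected network on the seven features, and a
  10-model bootstrap ensemble.
- **Synthetic corpus generator** — plants the class structure the analysis
  studies (3.3× nonessential/essential first-intron length ratio, first/later
  GC-density ratios 1.35/1.22/1.13, ordered intron counts and splice-dialect
  probabilities, class-discriminative motifs) and emits FASTA/GFF3/labels so
  the real input path is exercised end to end.
- **Statistics** — notched-box group summaries, Mann–Whitney rank tests
  (exact by enumeration for n ≤ 12), figure-style report tables.

## Worked example

```r
library(IntronEss)

# a small labeled corpus with the planted class structure
corpus <- generate_corpus(default_config(scale = 0.5, seed = 1))
introns <- introns_table(corpus$genes)

feat <- intron_feature_table(introns, include_cpg = FALSE)
first <- feat$ordinal == 1
mlen <- tapply(feat$length[first], feat$category[first], mean)
round(mlen["nonessential"] / mlen["essential"], 2)
#> nonessential
#>         3.57

ess <- feat$category == "essential"
round(mean(feat$gc_density[ess & first]) /
      mean(feat$gc_density[ess & !first]), 2)
#> [1] 1.36
```

The first number is the recovered nonessential/essential ratio of mean
first-intron length (planted value 3.3; at 50 genes/class the log-normal
sampling noise leaves it at 3.57). The second is the first/later GC-motif
density ratio inside the essential class (planted 1.35). The full
pipeline — extraction from emitted FASTA/GFF3, CNN training, gene scoring,
feature ensemble and report tables — runs from one call:

```r
res <- run_end_to_end(run_config(out_dir = "run1", seed = 1,
                                 corpus_scale = 0.5, window_bp = 500,
                                 cnn = cnn_config(n_filters = 32, epochs = 10,
                                                  seed = 1)))
res$auc_report   # intron/majority/double/first-intron AUC panel
```

## Limitations

The package analyses synthetic corpora by default; adapters for real
Ensembl + OGEE downloads are deliberately out of scope, so no real-data
AUCs are claimed — the classifiers are validated on planted-signal corpora
at desk scale. See `vignettes/intron-essentiality.Rmd` for the model,
parameter and design discussion.
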