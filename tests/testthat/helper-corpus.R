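# Shared synthetic corpora, built once per test run and cached. The "big"
# corpus is the 2,000 genes/class study corpus (emitted to disk and
# re-extracted through the annotation path); the "small" corpus (200
# genes/class) backs the classifier checks.

.corpus_cache <- new.env(parent = emptyenv())

big_corpus_seed <- 2024L

# generated corpus -> emit -> extract -> label; returns both the planted and
# the re-extracted view plus the per-intron feature table
big_corpus <- function() {
  if (!is.null(.corpus_cache$big)) return(.corpus_cache$big)
  corpus <- generate_corpus(default_config(scale = 20, seed = big_corpus_seed))
  dir <- file.path(tempdir(), "intrones-big-corpus")
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(big_corpus_seed + 1L)
  emit_corpus(corpus, dir)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  genome <- read_genome(file.path(dir, "genome.fa"))
  genes <- extract_introns(file.path(dir, "annotation.gff3"), genome)
  genes <- label_genes(genes, read_essentiality(file.path(dir, "labels.tsv")))
  introns <- introns_table(genes)
  feat <- intron_feature_table(introns, include_cpg = FALSE)
  .corpus_cache$big <- list(planted = corpus, genes = genes,
                            introns = introns, features = feat, dir = dir)
  .corpus_cache$big
}

small_corpus <- function() {
  if (!is.null(.corpus_cache$small)) return(.corpus_cache$small)
  corpus <- generate_corpus(default_config(scale = 2, seed = 77L))
  introns <- introns_table(corpus$genes)
  .corpus_cache$small <- list(corpus = corpus, introns = introns)
  .corpus_cache$small
}

# train/score both window models on the small corpus at the reduced design
# point (500-bp windows, 32 filters, 10 epochs); cached for reuse across the
# classifier checks
small_corpus_models <- function() {
  if (!is.null(.corpus_cache$models)) return(.corpus_cache$models)
  sc <- small_corpus()
  introns <- sc$introns[sc$introns$binary != "discarded", ]
  gene_bin <- introns[!duplicated(introns$gene_id), c("gene_id", "binary")]
  plan <- grouped_split(gene_bin$gene_id, gene_bin$binary,
                        test_fraction = 0.2, n_folds = 3L, seed = 77L)
  is_test <- introns$gene_id %in% split_genes(plan, "test")
  cfg <- cnn_config(n_filters = 32L, window = 16L, fc_units = 32L,
                    epochs = 10L, seed = 77L)
  out <- list(introns = introns, gene_bin = gene_bin, plan = plan,
              is_test = is_test, cfg = cfg, window_bp = 500L)
  for (kind in c("first", "last")) {
    win <- if (kind == "first") first_window(introns$sequence, 500L)
           else last_window(introns$sequence, 500L)
    codes <- encode_codes(win)
    model <- build_cnn(cfg, 500L, input_kind = paste0(kind, "_window"))
    model <- train_cnn(model, codes[!is_test, , drop = FALSE],
                       introns$binary[!is_test])
    scores <- score_introns(model, codes[is_test, , drop = FALSE])
    out[[paste0("codes_", kind)]] <- codes
    out[[paste0("model_", kind)]] <- model
    out[[paste0("scores_", kind)]] <- scores
  }
  .corpus_cache$models <- out
  out
}
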