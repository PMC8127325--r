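# End-to-end orchestration: simulate -> emit -> extract -> features ->
# train CNNs -> score -> evaluate -> feature model -> report. Every stage
# writes plain-text artifacts (FASTA/GFF3/TSV) into the run directory so any
# stage can be inspected or re-run independently, and the whole run is
# reproducible from the config snapshot alone.

#' Pipeline run configuration
#'
#' @param out_dir Run directory for all artifacts.
#' @param seed Master seed; stage seeds are derived from it.
#' @param corpus_scale Scale factor for [default_config()].
#' @param window_bp CNN input window length (bp).
#' @param cnn CNN configuration ([cnn_config()]).
#' @param feature_net Feature-network configuration
#'   ([feature_net_config()]).
#' @param test_fraction Held-out gene fraction.
#' @param include_cpg Compute CpG-island presence in the per-intron table.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, corpus_scale = 1,
                       window_bp = 1000L,
                       cnn = cnn_config(seed = seed),
                       feature_net = feature_net_config(seed = seed),
                       test_fraction = 0.2, include_cpg = FALSE) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 corpus_scale = corpus_scale,
                 window_bp = as.integer(window_bp),
                 cnn = cnn, feature_net = feature_net,
                 test_fraction = test_fraction, include_cpg = include_cpg),
            class = "run_config")
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline on a synthetic corpus
#'
#' Executes every stage in order, writing a config snapshot, the emitted
#' corpus, per-intron and per-gene feature tables, the gene-grouped split
#' plan, CNN training histories, intron/gene score tables, the AUC report,
#' the feature-ensemble AUC and the figure-style group report into
#' `config$out_dir`. With `resume = TRUE`, stages whose outputs already
#' exist are skipped.
#'
#' @param config A [run_config()].
#' @param resume Reuse existing stage outputs when present.
#' @param verbose Log stage progress to stderr.
#' @return Invisibly, a list with the main in-memory results (`auc_report`,
#'   `feature_auc`, paths).
#' @export
run_end_to_end <- function(config, resume = FALSE, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[pipeline] ", ...)
  path <- function(f) file.path(config$out_dir, f)

  snapshot <- config
  snapshot$cnn <- unclass(snapshot$cnn)
  snapshot$feature_net <- unclass(snapshot$feature_net)
  yaml::write_yaml(unclass(snapshot), path("config.yaml"))

  # stage 1: simulate + emit
  if (!(resume && file.exists(path("genome.fa")))) {
    say("simulate: generating corpus (scale ", config$corpus_scale, ")")
    corpus <- generate_corpus(default_config(config$corpus_scale,
                                             seed = config$seed))
    old <- local_rng(config$seed + 1L)
    emit_corpus(corpus, config$out_dir)
    restore_rng(old)
  } else say("simulate: reusing existing corpus")

  # stage 2: extract + label
  say("extract: reading genome + GFF3")
  genome <- read_genome(path("genome.fa"))
  genes <- extract_introns(path("annotation.gff3"), genome)
  labels <- read_essentiality(path("labels.tsv"))
  genes <- label_genes(genes, labels)
  write_gene_manifest(genes, path("genes.tsv"))
  introns <- introns_table(genes)

  # stage 3: features
  if (resume && file.exists(path("intron_features.tsv"))) {
    say("features: reusing existing tables")
    feat <- utils::read.delim(path("intron_features.tsv"))
    gene_feat <- utils::read.delim(path("gene_features.tsv"))
  } else {
    say("features: per-intron and per-gene feature tables")
    feat <- intron_feature_table(introns, include_cpg = config$include_cpg)
    gene_feat <- gene_feature_table(introns)
    write_tsv(feat[, setdiff(names(feat), "sequence")],
              path("intron_features.tsv"))
    write_tsv(gene_feat, path("gene_features.tsv"))
  }

  # stage 4: split (binary task drops discarded conditional genes)
  say("split: gene-grouped train/test plan")
  gene_bin <- introns[!duplicated(introns$gene_id),
                      c("gene_id", "binary")]
  gene_bin <- gene_bin[gene_bin$binary != "discarded", ]
  plan <- grouped_split(gene_bin$gene_id, gene_bin$binary,
                        test_fraction = config$test_fraction,
                        seed = config$seed)
  write_tsv(plan, path("split_plan.tsv"))

  keep <- introns$gene_id %in% gene_bin$gene_id
  sub <- introns[keep, ]
  is_test <- sub$gene_id %in% split_genes(plan, "test")
  y <- sub$binary

  # stage 5: train first- and last-window CNNs
  say("train-cnn: encoding windows (", config$window_bp, " bp)")
  codes_first <- encode_codes(first_window(sub$sequence, config$window_bp))
  codes_last <- encode_codes(last_window(sub$sequence, config$window_bp))
  models <- list()
  for (kind in c("first", "last")) {
    say("train-cnn: ", kind, "-window model")
    codes <- if (kind == "first") codes_first else codes_last
    model <- build_cnn(config$cnn, config$window_bp,
                       input_kind = paste0(kind, "_window"))
    model <- train_cnn(model, codes[!is_test, , drop = FALSE], y[!is_test])
    models[[kind]] <- model
    write_tsv(model$history, path(paste0("history_", kind, ".tsv")))
  }

  # stage 6: score test introns
  say("score: test-set intron scores")
  tabs <- list()
  for (kind in c("first", "last")) {
    codes <- if (kind == "first") codes_first else codes_last
    s <- score_introns(models[[kind]], codes[is_test, , drop = FALSE])
    tabs[[kind]] <- score_table(sub$gene_id[is_test], sub$ordinal[is_test],
                                kind, s)
  }
  write_tsv(rbind(as.data.frame(tabs$first), as.data.frame(tabs$last)),
            path("scores.tsv"))

  # stage 7: evaluate
  say("evaluate: AUC report")
  lab_tab <- data.frame(gene_id = gene_bin$gene_id, binary = gene_bin$binary)
  auc_report <- evaluate_suite(tabs$first, tabs$last, lab_tab)
  write_tsv(auc_report, path("auc_report.tsv"))

  # stage 8: feature model on the same gene split
  say("train-feature-model: ensemble on per-gene features")
  gf <- gene_feat[gene_feat$binary != "discarded", ]
  gf_test <- gf$gene_id %in% split_genes(plan, "test")
  ens <- train_feature_ensemble(gf[!gf_test, ], gf$binary[!gf_test],
                                config$feature_net)
  fscore <- ensemble_predict(ens, gf[gf_test, ])
  feature_auc <- roc_auc(fscore, gf$binary[gf_test])$auc
  write_tsv(data.frame(measure = "feature_ensemble", level = "gene",
                       auc = feature_auc, n = sum(gf_test)),
            path("feature_auc.tsv"))

  # stage 9: figure-style report
  say("report: group summaries and rank tests")
  rep <- build_report(feat, gene_feat)
  write_tsv(rep$groups, path("report_groups.tsv"))
  write_tsv(rep$proportions, path("report_proportions.tsv"))
  write_tsv(rep$gene_level, path("report_gene_level.tsv"))
  write_tsv(rep$tests, path("report_tests.tsv"))

  say("done: artifacts in ", config$out_dir)
  invisible(list(auc_report = auc_report, feature_auc = feature_auc,
                 out_dir = config$out_dir))
}
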