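test_that("the default configuration satisfies every planted invariant", {
  cfg <- default_config()
  expect_silent(validate_corpus_config(cfg))
  expect_equal(cfg$nonessential$first_len_mean / cfg$essential$first_len_mean,
               3.3)
  gcr <- function(p) p$gc_density_first / p$gc_density_later
  expect_equal(gcr(cfg$essential), 1.35)
  expect_equal(gcr(cfg$conditional), 1.22)
  expect_equal(gcr(cfg$nonessential), 1.13)
  expect_true(cfg$essential$intron_count_mean >
                cfg$conditional$intron_count_mean)
  expect_true(cfg$conditional$intron_count_mean >
                cfg$nonessential$intron_count_mean)
  expect_true(cfg$essential$p_unusual_5p < cfg$conditional$p_unusual_5p)
  expect_true(cfg$conditional$p_unusual_5p < cfg$nonessential$p_unusual_5p)
  expect_error(default_config(scale = 0), "positive")
  # a broken config is rejected with the violation named
  bad <- cfg
  bad$essential$gc_density_first <- 0.09
  expect_error(validate_corpus_config(bad), "1.35")
  # round trip through the YAML config format
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(rapply(unclass(cfg), unclass, how = "replace"), f)
  back <- yaml::read_yaml(f)
  expect_equal(back$essential$first_len_mean, cfg$essential$first_len_mean)
  expect_equal(back$nonessential$motif, cfg$nonessential$motif)
})

test_that("synthesized introns respect boundaries and composition limits", {
  set.seed(701)
  s <- synthesize_intron(500L, 0.08, 0.42)
  expect_equal(nchar(s), 500L)
  expect_identical(substr(s, 1, 2), "GT")
  expect_identical(substr(s, 499, 500), "AG")
  u <- synthesize_intron(500L, 0.08, 0.42, unusual_5p = TRUE,
                         unusual_3p = TRUE)
  expect_false(substr(u, 1, 2) == "GT")
  expect_false(substr(u, 499, 500) == "AG")
  # target 0 and zero background GC: no G or C outside boundary pairs
  s0 <- synthesize_intron(300L, 0, 1e-9)
  body <- substr(s0, 3, 298)
  expect_false(grepl("[GC]", body))
  expect_error(synthesize_intron(500L, 0.6, 0.42), "infeasible")
  expect_error(synthesize_intron(10L, 0.05, 0.4,
                                 motif = "TTACGTAACGGTTACG",
                                 motif_insert_rate = 0.01), ">= 4")
})

test_that("GC-motif density calibration hits the target in expectation", {
  set.seed(702)
  n <- 10000L
  seqs <- vapply(seq_len(n), function(i) synthesize_intron(1000L, 0.08, 0.42),
                 character(1))
  d <- gc_motif_density(seqs)
  se <- stats::sd(d) / sqrt(n)
  expect_lt(abs(mean(d) - 0.08), 2 * se)
})

test_that("corpora are seed-deterministic with exact class counts", {
  cfg <- default_config(scale = 0.2, seed = 19)
  a <- generate_corpus(cfg)
  b <- generate_corpus(cfg)
  expect_identical(a, b)
  cls <- vapply(a$genes, `[[`, character(1), "category")
  expect_equal(unname(table(cls)[c("essential", "conditional",
                                   "nonessential")]),
               rep(20L, 3), ignore_attr = TRUE)
  # conditional genes split into kept-essential and discarded by the rule
  bin <- vapply(a$genes, `[[`, character(1), "binary")
  expect_true(all(bin[cls == "essential"] == "essential"))
  expect_true(all(bin[cls == "nonessential"] == "nonessential"))
  expect_true(all(bin[cls == "conditional"] %in% c("essential", "discarded")))
})

test_that("essential introns carry their class motif at a higher rate", {
  sc <- small_corpus()
  introns <- sc$introns
  cfg <- default_config()
  ess_motif <- cfg$essential$motif
  count_in <- function(cls) {
    seqs <- introns$sequence[introns$category == cls]
    sum(Biostrings::vcountPattern(
      ess_motif, Biostrings::DNAStringSet(seqs))) / sum(nchar(seqs))
  }
  expect_gt(count_in("essential"), 5 * count_in("nonessential"))
})

test_that("emitted corpora round-trip exactly through extraction", {
  corpus <- generate_corpus(default_config(scale = 0.15, seed = 23))
  dir <- tempfile("emit")
  set.seed(24)
  paths <- emit_corpus(corpus, dir)
  expect_true(all(file.exists(unlist(paths))))
  genome <- read_genome(paths$genome)
  genes <- extract_introns(paths$gff, genome)
  genes <- label_genes(genes, read_essentiality(paths$labels))
  expect_equal(length(genes), length(corpus$genes))  # gene count preserved
  orig <- introns_table(corpus$genes)
  got <- introns_table(genes)
  key <- function(x) paste(x$gene_id, x$ordinal)
  m <- match(key(orig), key(got))
  expect_false(anyNA(m))
  expect_identical(got$sequence[m], orig$sequence)
  # minus-strand genes exercised and recovered via reverse complement
  strands <- vapply(corpus$genes, `[[`, character(1), "strand")
  expect_gt(sum(strands == "-"), 0L)
  minus_ids <- names(strands)[strands == "-"]
  sel <- orig$gene_id %in% minus_ids
  expect_identical(got$sequence[m][sel], orig$sequence[sel])
})

test_that("planted class structure survives the feature pipeline", {
  feat <- big_corpus()$features
  first <- feat$ordinal == 1L
  mlen <- tapply(feat$length[first], feat$category[first], mean)
  expect_equal(unname(mlen["nonessential"] / mlen["essential"]), 3.3,
               tolerance = 0.05)
  # orderings: intron counts and unusual-splice proportions
  n_introns <- tapply(feat$ordinal, feat$gene_id, max)
  cls <- feat$category[match(names(n_introns), feat$gene_id)]
  cnt <- tapply(n_introns, cls, mean)
  expect_true(cnt["essential"] > cnt["conditional"])
  expect_true(cnt["conditional"] > cnt["nonessential"])
  p5 <- tapply(feat$unusual_5p, feat$category, mean)
  expect_true(p5["essential"] < p5["conditional"])
  expect_true(p5["conditional"] < p5["nonessential"])
})
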