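test_that("read_genome parses records, uppercases, and rejects bad input", {
  fa <- tempfile(fileext = ".fa")
  set.seed(101)
  c1 <- random_dna(100)
  c2 <- random_dna(50)
  write_fasta(list(c1 = tolower(c1), c2 = c2), fa)
  genome <- read_genome(fa)
  expect_setequal(names(genome), c("c1", "c2"))
  # independent line-by-line reader
  lines <- readLines(fa)
  raw <- toupper(lines[!startsWith(lines, ">")])
  expect_identical(as.character(genome[["c1"]]), raw[1])
  expect_identical(as.character(genome[["c2"]]), raw[2])
  expect_equal(unname(BiocGenerics::width(genome)), c(100L, 50L))

  bad <- tempfile(fileext = ".fa")
  writeLines(c("ACGT", ">x", "ACGT"), bad)
  expect_error(read_genome(bad), "line 1")
  dup <- tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT", ">a", "GGGG"), dup)
  expect_error(read_genome(dup), "duplicate contig")
})

test_that("extract_introns finds exon gaps on the plus strand", {
  set.seed(102)
  contig <- random_dna(300)
  fa <- write_fasta(list(c1 = contig), tempfile(fileext = ".fa"))
  gff <- write_gff3(rbind(
    feat_row("c1", "gene", 1, 300, "+", "g1"),
    feat_row("c1", "mRNA", 1, 300, "+", "g1.t1", "g1"),
    feat_row("c1", "exon", 1, 100, "+", "e1", "g1.t1"),
    feat_row("c1", "exon", 201, 300, "+", "e2", "g1.t1"),
    feat_row("c1", "CDS", 1, 100, "+", "cd1", "g1.t1"),
    feat_row("c1", "CDS", 201, 300, "+", "cd2", "g1.t1")),
    tempfile(fileext = ".gff3"))
  genes <- extract_introns(gff, read_genome(fa))
  expect_length(genes, 1L)
  introns <- genes[["g1"]]$introns
  expect_equal(nrow(introns), 1L)
  expect_equal(introns$ordinal, 1L)
  expect_equal(introns$length, 100L)
  expect_identical(introns$sequence, substr(contig, 101, 200))
})

test_that("minus-strand introns are reverse-complemented and reordered", {
  # 10-bp toy intron; hand reverse complement
  intron_plus <- "GTTTCCAAAG"
  rc_by_hand <- "CTTTGGAAAC"
  set.seed(103)
  left <- random_dna(20); right <- random_dna(20)
  contig <- paste0(left, intron_plus, right)
  fa <- write_fasta(list(c1 = contig), tempfile(fileext = ".fa"))
  gff <- write_gff3(rbind(
    feat_row("c1", "gene", 1, 50, "-", "g1"),
    feat_row("c1", "mRNA", 1, 50, "-", "g1.t1", "g1"),
    feat_row("c1", "exon", 1, 20, "-", "e1", "g1.t1"),
    feat_row("c1", "exon", 31, 50, "-", "e2", "g1.t1"),
    feat_row("c1", "CDS", 1, 20, "-", "cd1", "g1.t1")),
    tempfile(fileext = ".gff3"))
  genes <- extract_introns(gff, read_genome(fa))
  expect_identical(genes[["g1"]]$introns$sequence, rc_by_hand)
})

test_that("the longest-CDS transcript contributes the introns", {
  set.seed(104)
  contig <- random_dna(700)
  fa <- write_fasta(list(c1 = contig), tempfile(fileext = ".fa"))
  # t1: CDS total 150 bp, exons 1-100 / 151-200; t2: CDS 300 bp, 1-200 / 301-400
  gff <- write_gff3(rbind(
    feat_row("c1", "gene", 1, 400, "+", "g1"),
    feat_row("c1", "mRNA", 1, 200, "+", "g1.t1", "g1"),
    feat_row("c1", "exon", 1, 100, "+", "e11", "g1.t1"),
    feat_row("c1", "exon", 151, 200, "+", "e12", "g1.t1"),
    feat_row("c1", "CDS", 1, 100, "+", "c11", "g1.t1"),
    feat_row("c1", "CDS", 151, 200, "+", "c12", "g1.t1"),
    feat_row("c1", "mRNA", 1, 400, "+", "g1.t2", "g1"),
    feat_row("c1", "exon", 1, 200, "+", "e21", "g1.t2"),
    feat_row("c1", "exon", 301, 400, "+", "e22", "g1.t2"),
    feat_row("c1", "CDS", 1, 200, "+", "c21", "g1.t2"),
    feat_row("c1", "CDS", 301, 400, "+", "c22", "g1.t2")),
    tempfile(fileext = ".gff3"))
  genes <- extract_introns(gff, read_genome(fa))
  introns <- genes[["g1"]]$introns
  expect_identical(unique(introns$transcript_id), "g1.t2")
  expect_identical(introns$sequence, substr(contig, 201, 300))
})

test_that("overlapping exons and out-of-contig coordinates are rejected", {
  set.seed(105)
  fa <- write_fasta(list(c1 = random_dna(100)), tempfile(fileext = ".fa"))
  gff <- write_gff3(rbind(
    feat_row("c1", "gene", 1, 90, "+", "g1"),
    feat_row("c1", "mRNA", 1, 90, "+", "g1.t1", "g1"),
    feat_row("c1", "exon", 1, 50, "+", "e1", "g1.t1"),
    feat_row("c1", "exon", 40, 90, "+", "e2", "g1.t1"),
    feat_row("c1", "CDS", 1, 50, "+", "c1x", "g1.t1")),
    tempfile(fileext = ".gff3"))
  expect_error(extract_introns(gff, read_genome(fa)), "g1\\.t1")

  gff2 <- write_gff3(rbind(
    feat_row("c1", "gene", 1, 500, "+", "g1"),
    feat_row("c1", "mRNA", 1, 500, "+", "g1.t1", "g1"),
    feat_row("c1", "exon", 1, 50, "+", "e1", "g1.t1"),
    feat_row("c1", "exon", 400, 500, "+", "e2", "g1.t1"),
    feat_row("c1", "CDS", 1, 50, "+", "c1x", "g1.t1")),
    tempfile(fileext = ".gff3"))
  expect_error(extract_introns(gff2, read_genome(fa)), "outside contig")
})

test_that("study-count tables are validated and parsed", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tn_essential\tn_total\tcategory",
               "g1\t10\t10\tessential",
               "g2\t0\t12\tnonessential"), tsv)
  tab <- read_essentiality(tsv)
  expect_equal(tab$n_essential, c(10L, 0L))
  expect_equal(tab$n_total, c(10L, 12L))
  expect_equal(tab$essential_fraction, c(1, 0))

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tn_essential\tn_total", "g1\tx\t10"), bad)
  expect_error(read_essentiality(bad), "row 1")
  over <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tn_essential\tn_total", "g1\t11\t10"), over)
  expect_error(read_essentiality(over), "n_essential > n_total")
  dup <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tn_essential\tn_total", "g1\t1\t10", "g1\t2\t10"), dup)
  expect_error(read_essentiality(dup), "duplicate")
})

test_that("the conditional-gene labeling rule matches the >= 50% grouping", {
  expect_identical(assign_label(10, 10, "essential")$binary, "essential")
  expect_identical(assign_label(0, 12, "nonessential")$binary, "nonessential")
  expect_identical(assign_label(3, 10, "conditional")$binary, "discarded")
  expect_identical(assign_label(6, 10, "conditional")$binary, "essential")
  # boundary: exactly half kept as essential by default, configurable
  expect_identical(assign_label(5, 10, "conditional")$binary, "essential")
  expect_identical(
    assign_label(5, 10, "conditional", half_is_essential = FALSE)$binary,
    "discarded")
  expect_error(assign_label(1, 0, "essential"), "n_total")
})

test_that("intron FASTA round trip preserves sequences and ordinals", {
  sc <- small_corpus()
  genes <- sc$corpus$genes[1:25]
  fa <- tempfile(fileext = ".fa")
  write_intron_fasta(genes, fa)
  back <- read_intron_fasta(fa)
  orig <- introns_table(genes)
  key <- function(x) paste(x$gene_id, x$ordinal)
  m <- match(key(orig), key(back))
  expect_false(anyNA(m))
  expect_identical(back$sequence[m], orig$sequence)
  expect_identical(back$ordinal[m], orig$ordinal)
})

test_that("intron and exon lengths partition the transcript span", {
  set.seed(106)
  contig <- random_dna(1000)
  fa <- write_fasta(list(c1 = contig), tempfile(fileext = ".fa"))
  gff <- write_gff3(rbind(
    feat_row("c1", "gene", 11, 910, "+", "g1"),
    feat_row("c1", "mRNA", 11, 910, "+", "g1.t1", "g1"),
    feat_row("c1", "exon", 11, 110, "+", "e1", "g1.t1"),
    feat_row("c1", "exon", 301, 400, "+", "e2", "g1.t1"),
    feat_row("c1", "exon", 861, 910, "+", "e3", "g1.t1"),
    feat_row("c1", "CDS", 11, 110, "+", "cx", "g1.t1")),
    tempfile(fileext = ".gff3"))
  genes <- extract_introns(gff, read_genome(fa))
  exon_bp <- 100 + 100 + 50
  intron_bp <- sum(genes[["g1"]]$introns$length)
  expect_equal(exon_bp + intron_bp, 910 - 11 + 1)
  # exactly one transcript contributes introns
  expect_identical(unique(genes[["g1"]]$introns$transcript_id), "g1.t1")
})
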