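# Synthetic gene/intron corpus generator. Plants the class structure the
# analysis studies: class-dependent intron counts, first-vs-later intron
# length distributions (nonessential/essential first-intron mean ratio 3.3),
# GC-motif-density first/later ratios (1.35 / 1.22 / 1.13 for essential /
# conditional / nonessential), class-ordered unusual splice-boundary
# probabilities, and class-discriminative sequence motifs that give the
# convolutional classifier learnable signal.

#' Per-class generator parameters
#'
#' @param n_genes Number of genes in the class.
#' @param intron_count_mean Mean intron count (shifted Poisson, minimum 1).
#' @param first_len_mean Mean first-intron length in bp (log-normal law).
#' @param later_len_mean Mean later-intron length in bp.
#' @param len_dispersion Log-normal sdlog of intron lengths.
#' @param gc_density_first Target GC-motif density (per bp) of first introns.
#' @param gc_density_later Target GC-motif density of later introns.
#' @param base_gc Background GC composition of generated sequence.
#' @param p_unusual_5p,p_unusual_3p Probability of a non-canonical 5'/3'
#'   splice boundary.
#' @param motif Class-discriminative motif string (must not contain the GC
#'   dinucleotide, so motif planting does not disturb the GC-density
#'   targets).
#' @param motif_insert_rate Expected motif copies per bp of intron.
#' @return A list of class `class_params`.
#' @export
class_params <- function(n_genes, intron_count_mean, first_len_mean,
                         later_len_mean, len_dispersion,
                         gc_density_first, gc_density_later, base_gc,
                         p_unusual_5p, p_unusual_3p,
                         motif, motif_insert_rate) {
  stopifnot(n_genes >= 1, intron_count_mean >= 1,
            first_len_mean > 0, later_len_mean > 0, len_dispersion > 0,
            gc_density_first >= 0, gc_density_later >= 0,
            base_gc > 0, base_gc < 1,
            p_unusual_5p >= 0, p_unusual_5p <= 1,
            p_unusual_3p >= 0, p_unusual_3p <= 1,
            motif_insert_rate >= 0)
  if (grepl("GC", motif, fixed = TRUE)) {
    stop("class motif must not contain the GC dinucleotide")
  }
  structure(list(n_genes = as.integer(n_genes),
                 intron_count_mean = intron_count_mean,
                 first_len_mean = first_len_mean,
                 later_len_mean = later_len_mean,
                 len_dispersion = len_dispersion,
                 gc_density_first = gc_density_first,
                 gc_density_later = gc_density_later,
                 base_gc = base_gc,
                 p_unusual_5p = p_unusual_5p, p_unusual_3p = p_unusual_3p,
                 motif = motif, motif_insert_rate = motif_insert_rate),
            class = "class_params")
}

#' Default synthetic-corpus configuration
#'
#' The defaults encode the planted study conditions: a 3.3-fold
#' nonessential/essential ratio of mean first-intron length; GC-motif-density
#' first/later ratios of 1.35 (essential), 1.22 (conditional) and 1.13
#' (nonessential); intron counts ordered essential > conditional >
#' nonessential; and unusual-splice probabilities ordered essential <
#' conditional < nonessential. Absolute lengths, base composition and motif
#' rates are generator choices documented in the methods vignette.
#'
#' @param scale Multiplies the per-class gene count (base 100 genes/class).
#' @param seed Integer seed for [generate_corpus()].
#' @return A list of class `corpus_config`.
#' @export
default_config <- function(scale = 1, seed = 1L) {
  if (scale <= 0) stop("scale must be positive")
  n <- as.integer(round(100 * scale))
  cfg <- structure(list(
    essential = class_params(
      n_genes = n, intron_count_mean = 7, first_len_mean = 2000,
      later_len_mean = 900, len_dispersion = 0.75,
      gc_density_first = 0.0810, gc_density_later = 0.0600,
      base_gc = 0.42, p_unusual_5p = 0.02, p_unusual_3p = 0.015,
      motif = "TTACGTAACGGTTACG", motif_insert_rate = 0.004),
    conditional = class_params(
      n_genes = n, intron_count_mean = 6, first_len_mean = 4000,
      later_len_mean = 1100, len_dispersion = 0.75,
      gc_density_first = 0.0732, gc_density_later = 0.0600,
      base_gc = 0.42, p_unusual_5p = 0.045, p_unusual_3p = 0.03,
      motif = "AGGTTCAAGGTTCAAG", motif_insert_rate = 0.004),
    nonessential = class_params(
      n_genes = n, intron_count_mean = 5, first_len_mean = 6600,
      later_len_mean = 1300, len_dispersion = 0.75,
      gc_density_first = 0.0678, gc_density_later = 0.0600,
      base_gc = 0.42, p_unusual_5p = 0.08, p_unusual_3p = 0.05,
      motif = "AATGGATTGAATCCAT", motif_insert_rate = 0.004),
    min_intron_len = 70L, seed = as.integer(seed)),
    class = "corpus_config")
  validate_corpus_config(cfg)
  cfg
}

#' Validate a corpus configuration against its planted-structure invariants
#'
#' @param config A `corpus_config`.
#' @return TRUE invisibly; otherwise an error listing every violation.
#' @export
validate_corpus_config <- function(config) {
  e <- config$essential; c_ <- config$conditional; n <- config$nonessential
  problems <- character()
  chk <- function(cond, msg) if (!cond) problems <<- c(problems, msg)
  ratio <- n$first_len_mean / e$first_len_mean
  chk(abs(ratio - 3.3) < 1e-6,
      sprintf("nonessential/essential first-intron mean ratio is %.3f, not 3.3",
              ratio))
  gc_ratio <- function(p) p$gc_density_first / p$gc_density_later
  chk(abs(gc_ratio(e) - 1.35) < 1e-6, "essential GC-density ratio != 1.35")
  chk(abs(gc_ratio(c_) - 1.22) < 1e-6, "conditional GC-density ratio != 1.22")
  chk(abs(gc_ratio(n) - 1.13) < 1e-6, "nonessential GC-density ratio != 1.13")
  chk(e$intron_count_mean > c_$intron_count_mean &&
        c_$intron_count_mean > n$intron_count_mean,
      "intron counts not ordered essential > conditional > nonessential")
  chk(e$p_unusual_5p < c_$p_unusual_5p && c_$p_unusual_5p < n$p_unusual_5p,
      "p_unusual_5p not ordered essential < conditional < nonessential")
  chk(e$p_unusual_3p < c_$p_unusual_3p && c_$p_unusual_3p < n$p_unusual_3p,
      "p_unusual_3p not ordered essential < conditional < nonessential")
  if (length(problems)) {
    stop("invalid corpus config:\n  ", paste(problems, collapse = "\n  "))
  }
  invisible(TRUE)
}

.non_gt_pairs <- setdiff(as.vector(outer(c("A", "C", "G", "T"),
                                         c("A", "C", "G", "T"), paste0)),
                         "GT")
.non_ag_pairs <- setdiff(as.vector(outer(c("A", "C", "G", "T"),
                                         c("A", "C", "G", "T"), paste0)),
                         "AG")

#' Synthesise one intron sequence
#'
#' Background bases are drawn iid at the requested GC composition; GC
#' dinucleotides are planted at a count calibrated (with randomised rounding)
#' so that, with canonical boundaries and no motif insertion, the expected
#' measured GC-motif density equals `gc_density_target` exactly. The first
#' two bases are "GT" unless `unusual_5p` (then a random non-GT pair) and the
#' last two are "AG" unless `unusual_3p`. Discriminative motif copies are
#' inserted at `motif_insert_rate` per bp at positions that avoid the
#' boundaries; motif bases slightly dilute the realised density, equally for
#' first and later introns.
#'
#' @param length Intron length in bp.
#' @param gc_density_target Target GC-motif density (per bp).
#' @param base_gc Background GC composition.
#' @param unusual_5p,unusual_3p Plant non-canonical boundaries?
#' @param motif Motif string (no "GC" allowed) or NULL.
#' @param motif_insert_rate Expected motif copies per bp.
#' @return A character scalar of `length` bases.
#' @export
synthesize_intron <- function(length, gc_density_target, base_gc,
                              unusual_5p = FALSE, unusual_3p = FALSE,
                              motif = NULL, motif_insert_rate = 0) {
  L <- as.integer(length)
  mlen <- if (is.null(motif)) 0L else nchar(motif)
  if (L < 4L + mlen) stop("intron length must be >= 4 + motif length")
  if (gc_density_target > 0.5) {
    stop("GC-motif density target > 0.5 is infeasible")
  }
  g <- base_gc
  bases <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                  prob = c((1 - g) / 2, g / 2, g / 2, (1 - g) / 2))

  motif_cover <- rep(FALSE, L)
  if (mlen > 0L && motif_insert_rate > 0) {
    n_copies <- stats::rpois(1, motif_insert_rate * L)
    if (n_copies > 0L && L - 2L - mlen >= 3L) {
      starts <- sort(sample(3:(L - 1L - mlen), min(n_copies, L), replace = TRUE))
      mchars <- strsplit(motif, "", fixed = TRUE)[[1]]
      last_end <- 0L
      for (s in starts) {
        if (s > last_end) {
          bases[s:(s + mlen - 1L)] <- mchars
          motif_cover[s:(s + mlen - 1L)] <- TRUE
          last_end <- s + mlen - 1L
        }
      }
    }
  }

  # plant GC dinucleotides in disjoint 3-bp slots of the interior so that
  # E[#GC occurrences] = target * L (exact for canonical boundaries and no
  # motif insertion; see the calibration in the methods vignette)
  q <- (g / 2)^2
  S <- (L - 4L) %/% 3L
  if (S >= 1L && gc_density_target > 0) {
    k_real <- (gc_density_target * L - q * (L - 5)) / (1 - 3 * q + q / S)
    k <- floor(k_real) + (stats::runif(1) < (k_real - floor(k_real)))
    k <- as.integer(k)
    if (k > S) {
      stop("GC-motif density target ", gc_density_target,
           " infeasible at length ", L)
    }
    if (k > 0L) {
      slot_starts <- 3L + 3L * (seq_len(S) - 1L)
      free <- !motif_cover[slot_starts] & !motif_cover[slot_starts + 1L]
      avail <- slot_starts[free]
      chosen <- if (length(avail) <= k) avail else
        avail[sample.int(length(avail), k)]
      bases[chosen] <- "G"
      bases[chosen + 1L] <- "C"
    }
  }

  five <- if (unusual_5p) sample(.non_gt_pairs, 1) else "GT"
  three <- if (unusual_3p) sample(.non_ag_pairs, 1) else "AG"
  bases[1:2] <- strsplit(five, "")[[1]]
  bases[(L - 1L):L] <- strsplit(three, "")[[1]]
  paste(bases, collapse = "")
}

# intron lengths for one gene: first intron from the first-length law,
# later introns from the later-length law (log-normal, mean-parameterised)
draw_lengths <- function(n_introns, params, min_len) {
  meanlog_first <- log(params$first_len_mean) - params$len_dispersion^2 / 2
  meanlog_later <- log(params$later_len_mean) - params$len_dispersion^2 / 2
  lens <- numeric(n_introns)
  lens[1] <- stats::rlnorm(1, meanlog_first, params$len_dispersion)
  if (n_introns > 1L) {
    lens[-1] <- stats::rlnorm(n_introns - 1L, meanlog_later,
                              params$len_dispersion)
  }
  pmax(as.integer(round(lens)), min_len)
}

#' Generate a labeled synthetic corpus
#'
#' Draws, per class, the configured number of genes with shifted-Poisson
#' intron counts, log-normal first/later intron lengths (floored at
#' `min_intron_len`), and sequences from [synthesize_intron()]. Essential
#' genes get study counts 10/10, nonessential 0/10, and conditional genes a
#' uniform study fraction so the >= 50 % grouping rule is exercised. The
#' corpus is bit-identical under the same config (seed included).
#'
#' @param config A `corpus_config` from [default_config()].
#' @return A list with `genes` (list of labeled `gene_record`s) and `labels`
#'   (the OGEE-style study-count table).
#' @export
generate_corpus <- function(config) {
  validate_corpus_config(config)
  old <- local_rng(config$seed)
  on.exit(restore_rng(old))
  classes <- c("essential", "conditional", "nonessential")
  prefix <- c(essential = "GE", conditional = "GC", nonessential = "GN")
  genes <- list()
  lab_rows <- list()
  for (cls in classes) {
    p <- config[[cls]]
    for (i in seq_len(p$n_genes)) {
      gene_id <- sprintf("%s%05d", prefix[[cls]], i)
      n_int <- 1L + stats::rpois(1, p$intron_count_mean - 1)
      lens <- draw_lengths(n_int, p, config$min_intron_len)
      u5 <- stats::runif(n_int) < p$p_unusual_5p
      u3 <- stats::runif(n_int) < p$p_unusual_3p
      targets <- c(p$gc_density_first,
                   rep(p$gc_density_later, max(0L, n_int - 1L)))
      seqs <- vapply(seq_len(n_int), function(j) {
        synthesize_intron(lens[j], targets[j], p$base_gc, u5[j], u3[j],
                          motif = p$motif,
                          motif_insert_rate = p$motif_insert_rate)
      }, character(1))
      n_tot <- 10L
      n_ess <- switch(cls, essential = 10L, nonessential = 0L,
                      conditional = sample(1:9, 1))
      introns <- data.frame(transcript_id = paste0(gene_id, ".t1"),
                            ordinal = seq_len(n_int),
                            sequence = seqs, length = lens,
                            stringsAsFactors = FALSE)
      lab <- assign_label(n_ess, n_tot, cls)
      strand <- if (stats::runif(1) < 0.5) "+" else "-"
      genes[[gene_id]] <- new_gene_record(gene_id, strand, introns,
                                          category = cls,
                                          binary = lab$binary,
                                          essential_fraction =
                                            lab$essential_fraction)
      lab_rows[[gene_id]] <- data.frame(gene_id = gene_id,
                                        n_essential = n_ess,
                                        n_total = n_tot, category = cls,
                                        stringsAsFactors = FALSE)
    }
  }
  labels <- do.call(rbind, lab_rows)
  rownames(labels) <- NULL
  list(genes = genes, labels = labels)
}

#' Emit a synthetic corpus as genome FASTA + GFF3 + label table
#'
#' Embeds each gene's introns between short generated exons on synthetic
#' contigs (minus-strand genes are written reverse-complemented in genomic
#' orientation), writes a GFF3 with gene/mRNA/exon/CDS features and the
#' OGEE-style label TSV, such that [extract_introns()] recovers every intron
#' sequence exactly.
#'
#' @param corpus A corpus from [generate_corpus()].
#' @param out_dir Output directory (created if needed).
#' @param exon_len Length of each generated exon (bp).
#' @param spacer Intergenic spacer length (bp).
#' @param genes_per_contig Genes placed per synthetic contig.
#' @return Invisibly, a list with paths `genome`, `gff`, `labels`.
#' @export
emit_corpus <- function(corpus, out_dir, exon_len = 150L, spacer = 200L,
                        genes_per_contig = 200L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genes <- corpus$genes
  n_genes <- length(genes)
  n_contigs <- ceiling(n_genes / genes_per_contig)
  contig_of <- rep(seq_len(n_contigs), each = genes_per_contig)[1:n_genes]
  contig_names <- sprintf("ctg%03d", seq_len(n_contigs))

  spacer_seq <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                 prob = c(0.29, 0.21, 0.21, 0.29)), collapse = "")
  }

  gff_rows <- vector("list", n_genes)
  offsets <- integer(n_contigs)
  pieces <- lapply(seq_len(n_contigs), function(i) list())

  for (gi in seq_len(n_genes)) {
    g <- genes[[gi]]
    ci <- contig_of[gi]
    n_int <- nrow(g$introns)
    exons <- vapply(seq_len(n_int + 1L), function(j) spacer_seq(exon_len),
                    character(1))
    # transcript-order pieces: E1 I1 E2 I2 ... E(n+1)
    tx_pieces <- character(2L * n_int + 1L)
    tx_pieces[seq(1L, 2L * n_int + 1L, by = 2L)] <- exons
    if (n_int > 0L) {
      tx_pieces[seq(2L, 2L * n_int, by = 2L)] <- g$introns$sequence
    }
    tx_seq <- paste(tx_pieces, collapse = "")
    Tlen <- nchar(tx_seq)
    genomic <- if (g$strand == "+") tx_seq else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(tx_seq)))

    lead <- spacer_seq(spacer)
    off <- offsets[ci] + spacer  # gene starts after the spacer
    pieces[[ci]] <- c(pieces[[ci]], list(lead, genomic))
    offsets[ci] <- off + Tlen

    # exon coordinates in transcript order
    piece_len <- nchar(tx_pieces)
    cum <- cumsum(c(0L, piece_len))[seq_along(piece_len)]
    exon_idx <- seq(1L, 2L * n_int + 1L, by = 2L)
    tx_start <- cum[exon_idx] + 1L
    tx_end <- cum[exon_idx] + piece_len[exon_idx]
    if (g$strand == "+") {
      gstart <- off + tx_start
      gend <- off + tx_end
    } else {
      gstart <- off + Tlen - tx_end + 1L
      gend <- off + Tlen - tx_start + 1L
    }
    o <- order(gstart)
    gstart <- gstart[o]; gend <- gend[o]
    chrom <- contig_names[ci]
    tx_id <- paste0(g$gene_id, ".t1")
    attr_gene <- paste0("ID=", g$gene_id)
    attr_tx <- paste0("ID=", tx_id, ";Parent=", g$gene_id)
    attr_exon <- paste0("ID=", tx_id, ".e", seq_along(gstart),
                        ";Parent=", tx_id)
    attr_cds <- paste0("ID=", tx_id, ".c", seq_along(gstart),
                       ";Parent=", tx_id)
    gff_rows[[gi]] <- data.frame(
      seqid = chrom, source = "IntronEss",
      type = c("gene", "mRNA", rep("exon", length(gstart)),
               rep("CDS", length(gstart))),
      start = c(off + 1L, off + 1L, gstart, gstart),
      end = c(off + Tlen, off + Tlen, gend, gend),
      score = ".", strand = g$strand,
      phase = c(".", ".", rep(".", length(gstart)),
                rep("0", length(gstart))),
      attributes = c(attr_gene, attr_tx, attr_exon, attr_cds),
      stringsAsFactors = FALSE)
  }

  contigs <- vapply(pieces, function(pl) paste(unlist(pl), collapse = ""),
                    character(1))
  genome <- Biostrings::DNAStringSet(contigs)
  names(genome) <- contig_names

  genome_path <- file.path(out_dir, "genome.fa")
  gff_path <- file.path(out_dir, "annotation.gff3")
  labels_path <- file.path(out_dir, "labels.tsv")
  Biostrings::writeXStringSet(genome, genome_path)
  gff <- do.call(rbind, gff_rows)
  con <- file(gff_path, "w")
  writeLines("##gff-version 3", con)
  utils::write.table(gff, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  close(con)
  utils::write.table(corpus$labels, labels_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(genome = genome_path, gff = gff_path, labels = labels_path))
}
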