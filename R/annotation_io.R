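#' Read a genome FASTA file
#'
#' Reads a multi-record genome FASTA into a named [Biostrings::DNAStringSet].
#' Sequences are case-normalised to uppercase (the DNA alphabet), and contig
#' ids must be unique.
#'
#' @param fasta_path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by contig id (the first
#'   whitespace-delimited token of each header line).
#' @export
read_genome <- function(fasta_path) {
  if (!file.exists(fasta_path)) {
    stop("genome FASTA not found: ", fasta_path)
  }
  first <- readLines(fasta_path, n = 1L)
  if (length(first) == 0L || !startsWith(first, ">")) {
    stop("malformed FASTA (line 1): expected a '>' header in ", fasta_path)
  }
  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (anyDuplicated(names(genome))) {
    dups <- unique(names(genome)[duplicated(names(genome))])
    stop("duplicate contig id(s) in FASTA: ", paste(dups, collapse = ", "))
  }
  genome
}

#' Read an OGEE-style gene essentiality table
#'
#' The table is delimited text with a header and one row per gene, giving the
#' number of studies that called the gene essential and the total number of
#' studies, plus the three-way category used for the feature analysis.
#'
#' @param table_path Path to a TSV with columns `gene_id`, `n_essential`,
#'   `n_total` and optionally `category`.
#' @return A data.frame with columns `gene_id`, `n_essential`, `n_total`,
#'   `category`, `essential_fraction`.
#' @export
read_essentiality <- function(table_path) {
  tab <- utils::read.delim(table_path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  required <- c("gene_id", "n_essential", "n_total")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("essentiality table missing column(s): ", paste(missing, collapse = ", "))
  }
  n_ess <- suppressWarnings(as.integer(tab$n_essential))
  n_tot <- suppressWarnings(as.integer(tab$n_total))
  bad <- which(is.na(n_ess) | is.na(n_tot))
  if (length(bad)) {
    stop("non-integer study count in essentiality table, row ", bad[1],
         " (gene ", tab$gene_id[bad[1]], ")")
  }
  if (any(n_ess < 0L | n_tot < 0L)) {
    stop("negative study count in essentiality table")
  }
  over <- which(n_ess > n_tot)
  if (length(over)) {
    stop("n_essential > n_total in essentiality table, row ", over[1],
         " (gene ", tab$gene_id[over[1]], ")")
  }
  if (anyDuplicated(tab$gene_id)) {
    stop("duplicate gene id(s) in essentiality table: ",
         paste(unique(tab$gene_id[duplicated(tab$gene_id)]), collapse = ", "))
  }
  category <- if ("category" %in% names(tab)) tab$category else
    ifelse(n_ess == n_tot, "essential",
           ifelse(n_ess == 0L, "nonessential", "conditional"))
  data.frame(gene_id = tab$gene_id, n_essential = n_ess, n_total = n_tot,
             category = category,
             essential_fraction = ifelse(n_tot > 0L, n_ess / n_tot, NA_real_),
             stringsAsFactors = FALSE)
}

#' Assign the binary essentiality label for a gene
#'
#' Essential genes map to binary "essential" and nonessential genes to binary
#' "nonessential". Conditional genes (those on which studies disagree) are
#' grouped with essential genes when the fraction of studies calling them
#' essential reaches `conditional_threshold`, and discarded otherwise. At
#' exactly the threshold the gene is kept as essential; set
#' `half_is_essential = FALSE` to discard the boundary case instead.
#'
#' @param n_essential Number of studies calling the gene essential.
#' @param n_total Total number of studies (>= 1).
#' @param category One of "essential", "conditional", "nonessential".
#' @param conditional_threshold Fraction of agreeing studies required for a
#'   conditional gene to count as essential (default 0.5).
#' @param half_is_essential Keep a conditional gene whose fraction equals the
#'   threshold (default TRUE).
#' @return A list with `category`, `binary` (one of "essential",
#'   "nonessential", "discarded") and `essential_fraction`.
#' @export
assign_label <- function(n_essential, n_total, category,
                         conditional_threshold = 0.5,
                         half_is_essential = TRUE) {
  if (n_total < 1L) stop("n_total must be >= 1")
  if (n_essential < 0L || n_essential > n_total) {
    stop("n_essential must lie in [0, n_total]")
  }
  category <- match.arg(category, c("essential", "conditional", "nonessential"))
  frac <- n_essential / n_total
  binary <- switch(category,
    essential = "essential",
    nonessential = "nonessential",
    conditional = {
      keep <- if (half_is_essential) frac >= conditional_threshold
              else frac > conditional_threshold
      if (keep) "essential" else "discarded"
    })
  list(category = category, binary = binary, essential_fraction = frac)
}

#' @keywords internal
new_gene_record <- function(gene_id, strand, introns,
                            category = NA_character_, binary = NA_character_,
                            essential_fraction = NA_real_) {
  stopifnot(strand %in% c("+", "-"))
  structure(
    list(gene_id = gene_id, strand = strand,
         category = category, binary = binary,
         essential_fraction = essential_fraction,
         introns = introns),
    class = "gene_record")
}

#' @export
print.gene_record <- function(x, ...) {
  cat(sprintf("<gene_record> %s (%s) %s/%s, %d intron(s)\n",
              x$gene_id, x$strand,
              x$category, x$binary, nrow(x$introns)))
  invisible(x)
}

# Empty per-gene intron table (one row per intron, transcript 5'->3' order).
empty_intron_table <- function() {
  data.frame(transcript_id = character(), ordinal = integer(),
             sequence = character(), length = integer(),
             stringsAsFactors = FALSE)
}

#' Extract introns from a GFF3 annotation
#'
#' For each gene, the transcript with the longest total CDS is selected (ties
#' broken by lexicographically smallest transcript id) and its introns are the
#' gaps between consecutive exons. Minus-strand introns are stored
#' reverse-complemented so every sequence reads 5' to 3', and ordinals count
#' from the transcript 5' end.
#'
#' @param gff_path Path to a GFF3 file with gene/mRNA/exon/CDS features
#'   (1-based inclusive coordinates).
#' @param genome A named [Biostrings::DNAStringSet] from [read_genome()].
#' @return A list of `gene_record` objects (unlabeled), one per annotated
#'   gene, each carrying an ordered intron table. Intronless genes yield an
#'   empty intron table.
#' @export
extract_introns <- function(gff_path, genome) {
  gff <- rtracklayer::import(gff_path)
  type <- as.character(gff$type)

  is_tx <- type %in% c("mRNA", "transcript")
  tx_id <- as.character(gff$ID[is_tx])
  tx_parent <- vapply(gff$Parent[is_tx], function(p) p[1], character(1))
  tx_strand <- as.character(BiocGenerics::strand(gff))[is_tx]
  tx_chrom <- as.character(GenomicRanges::seqnames(gff))[is_tx]
  if (length(tx_id) == 0L) stop("no mRNA/transcript features in ", gff_path)

  parent1 <- function(p) if (length(p)) p[[1]] else NA_character_
  cds <- gff[type == "CDS"]
  cds_parent <- vapply(as.list(cds$Parent), parent1, character(1))
  cds_len_by_tx <- tapply(BiocGenerics::width(cds), cds_parent, sum)

  exons <- gff[type == "exon"]
  exon_parent <- vapply(as.list(exons$Parent), parent1, character(1))

  # choose, per gene, the transcript with maximal total CDS length
  cds_len <- ifelse(tx_id %in% names(cds_len_by_tx),
                    as.numeric(cds_len_by_tx[tx_id]), 0)
  ord <- order(tx_parent, -cds_len, tx_id)
  keep <- ord[!duplicated(tx_parent[ord])]
  chosen <- data.frame(gene_id = tx_parent[keep], transcript_id = tx_id[keep],
                       strand = tx_strand[keep], chrom = tx_chrom[keep],
                       stringsAsFactors = FALSE)

  exon_start <- BiocGenerics::start(exons)
  exon_end <- BiocGenerics::end(exons)
  exon_by_tx <- split(seq_along(exons), exon_parent)

  # pass 1: intron coordinates per chosen transcript (base R, vectorisable)
  coord <- list()
  for (i in seq_len(nrow(chosen))) {
    tx <- chosen$transcript_id[i]
    idx <- exon_by_tx[[tx]]
    if (is.null(idx) || length(idx) < 2L) next
    st <- sort(exon_start[idx])
    en <- exon_end[idx][order(exon_start[idx])]
    if (any(st[-1] <= en[-length(en)])) {
      stop("overlapping or unsorted exons in transcript ", tx)
    }
    int_start <- en[-length(en)] + 1L
    int_end <- st[-1] - 1L
    ok <- int_end >= int_start
    if (!any(ok)) next
    coord[[tx]] <- data.frame(row = i, start = int_start[ok],
                              end = int_end[ok])
  }

  records <- lapply(seq_len(nrow(chosen)), function(i)
    new_gene_record(chosen$gene_id[i], chosen$strand[i],
                    empty_intron_table()))
  names(records) <- chosen$gene_id
  if (length(coord)) {
    all_coord <- do.call(rbind, coord)
    all_coord$chrom <- chosen$chrom[all_coord$row]
    contig_len <- stats::setNames(BiocGenerics::width(genome), names(genome))
    bad_contig <- !all_coord$chrom %in% names(genome)
    if (any(bad_contig)) {
      stop("contig ", all_coord$chrom[bad_contig][1], " for transcript ",
           chosen$transcript_id[all_coord$row[bad_contig][1]],
           " not in genome")
    }
    outside <- all_coord$end > contig_len[all_coord$chrom]
    if (any(outside)) {
      stop("intron coordinates outside contig ",
           all_coord$chrom[outside][1], " for transcript ",
           chosen$transcript_id[all_coord$row[outside][1]])
    }
    # pass 2: one batched extraction per contig
    all_coord$sequence <- NA_character_
    for (chrom in unique(all_coord$chrom)) {
      sel <- which(all_coord$chrom == chrom)
      seqs <- Biostrings::extractAt(
        genome[[chrom]],
        IRanges::IRanges(all_coord$start[sel], all_coord$end[sel]))
      all_coord$sequence[sel] <- as.character(seqs)
    }
    minus <- chosen$strand[all_coord$row] == "-"
    if (any(minus)) {
      all_coord$sequence[minus] <- as.character(
        Biostrings::reverseComplement(
          Biostrings::DNAStringSet(all_coord$sequence[minus])))
    }
    # pass 3: assemble per-gene tables (5'->3' ordinals)
    by_row <- split(seq_len(nrow(all_coord)), all_coord$row)
    for (key in names(by_row)) {
      i <- as.integer(key)
      sel <- by_row[[key]]
      seq_chr <- all_coord$sequence[sel]
      if (chosen$strand[i] == "-") seq_chr <- rev(seq_chr)
      records[[i]]$introns <- data.frame(
        transcript_id = chosen$transcript_id[i],
        ordinal = seq_along(seq_chr),
        sequence = seq_chr, length = nchar(seq_chr),
        stringsAsFactors = FALSE)
    }
  }
  records
}

#' Attach essentiality labels to extracted gene records
#'
#' @param genes List of `gene_record` objects from [extract_introns()].
#' @param labels Data.frame from [read_essentiality()].
#' @inheritParams assign_label
#' @return The gene list with `category`, `binary` and `essential_fraction`
#'   filled in; genes absent from the label table are dropped with a warning.
#' @export
label_genes <- function(genes, labels, conditional_threshold = 0.5,
                        half_is_essential = TRUE) {
  ids <- vapply(genes, `[[`, character(1), "gene_id")
  known <- ids %in% labels$gene_id
  if (!all(known)) {
    warning(sum(!known), " gene(s) without essentiality labels dropped")
    genes <- genes[known]
    ids <- ids[known]
  }
  m <- match(ids, labels$gene_id)
  for (i in seq_along(genes)) {
    lab <- assign_label(labels$n_essential[m[i]], labels$n_total[m[i]],
                        labels$category[m[i]],
                        conditional_threshold, half_is_essential)
    genes[[i]]$category <- lab$category
    genes[[i]]$binary <- lab$binary
    genes[[i]]$essential_fraction <- lab$essential_fraction
  }
  genes
}

#' Flatten gene records into a per-intron table
#'
#' @param genes List of `gene_record` objects.
#' @return A data.frame with one row per intron: `gene_id`, `transcript_id`,
#'   `ordinal`, `sequence`, `length`, `strand`, `category`, `binary`,
#'   `essential_fraction`.
#' @export
introns_table <- function(genes) {
  parts <- lapply(genes, function(g) {
    if (nrow(g$introns) == 0L) return(NULL)
    cbind(data.frame(gene_id = g$gene_id, stringsAsFactors = FALSE),
          g$introns,
          data.frame(strand = g$strand, category = g$category,
                     binary = g$binary,
                     essential_fraction = g$essential_fraction,
                     stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Write extracted introns to FASTA
#'
#' Headers follow `gene_id|transcript_id|ordinal|label`, where label is the
#' binary essentiality label (or NA for unlabeled genes).
#'
#' @param genes List of `gene_record` objects.
#' @param path Output FASTA path.
#' @return The path, invisibly.
#' @export
write_intron_fasta <- function(genes, path) {
  tab <- introns_table(genes)
  if (is.null(tab) || nrow(tab) == 0L) stop("no introns to write")
  seqs <- Biostrings::DNAStringSet(tab$sequence)
  names(seqs) <- paste(tab$gene_id, tab$transcript_id, tab$ordinal,
                       tab$binary, sep = "|")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read an intron FASTA written by [write_intron_fasta()]
#'
#' @param path FASTA path.
#' @return A per-intron data.frame with `gene_id`, `transcript_id`, `ordinal`,
#'   `binary`, `sequence`, `length`.
#' @export
read_intron_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  bad <- which(lengths(parts) != 4L)
  if (length(bad)) {
    stop("malformed intron FASTA header at record ", bad[1])
  }
  fields <- do.call(rbind, parts)
  data.frame(gene_id = fields[, 1], transcript_id = fields[, 2],
             ordinal = as.integer(fields[, 3]), binary = fields[, 4],
             sequence = as.character(seqs), length = BiocGenerics::width(seqs),
             stringsAsFactors = FALSE)
}

#' Write the per-gene manifest TSV
#'
#' @param genes List of labeled `gene_record` objects.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_gene_manifest <- function(genes, path) {
  man <- data.frame(
    gene_id = vapply(genes, `[[`, character(1), "gene_id"),
    strand = vapply(genes, `[[`, character(1), "strand"),
    category = vapply(genes, `[[`, character(1), "category"),
    binary = vapply(genes, `[[`, character(1), "binary"),
    essential_fraction = vapply(genes, `[[`, numeric(1), "essential_fraction"),
    n_introns = vapply(genes, function(g) nrow(g$introns), integer(1)),
    stringsAsFactors = FALSE)
  utils::write.table(man, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
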