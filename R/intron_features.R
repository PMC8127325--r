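#' GC-motif density of a sequence
#'
#' Occurrences of the motif (default the dinucleotide "GC"), counted by an
#' exhaustive overlapping scan over every start position, divided by sequence
#' length. Positions holding N or any IUPAC ambiguity code never match.
#'
#' @param sequence Character vector of DNA sequences (uppercase A/C/G/T plus
#'   ambiguity codes).
#' @param motif Motif string (default "GC").
#' @return Numeric vector of per-bp densities.
#' @export
gc_motif_density <- function(sequence, motif = "GC") {
  check_nonempty(sequence)
  x <- Biostrings::DNAStringSet(sequence)
  counts <- Biostrings::vcountPattern(motif, x, fixed = TRUE)
  counts / BiocGenerics::width(x)
}

#' GC content of a sequence
#'
#' Fraction of bases that are literal G or C. Ambiguity codes are excluded
#' from the numerator but counted in the length.
#'
#' @inheritParams gc_motif_density
#' @return Numeric vector in \[0, 1\].
#' @export
gc_content <- function(sequence) {
  check_nonempty(sequence)
  x <- Biostrings::DNAStringSet(sequence)
  gc <- unname(Biostrings::letterFrequency(x, letters = "CG")[, 1])
  gc / BiocGenerics::width(x)
}

#' GC content with GC-motif content subtracted
#'
#' `(#G + #C - 2 * n_motif) / L`, i.e. the GC fraction after removing the
#' bases consumed by motif occurrences. Non-negative for the default "GC"
#' motif because overlapping occurrences are impossible.
#'
#' @inheritParams gc_motif_density
#' @return Numeric vector.
#' @export
gc_content_excl_motifs <- function(sequence, motif = "GC") {
  gc_content(sequence) - nchar(motif) * gc_motif_density(sequence, motif)
}

#' Classify the splice-site dialect of an intron
#'
#' Introns are stored strand-corrected 5' to 3'. The canonical boundaries are
#' a 5' "GT" dinucleotide and a 3' "AG" dinucleotide; anything else (including
#' ambiguity codes at the boundary) is flagged unusual.
#'
#' @param sequence Character vector of intron sequences, each of length >= 4.
#' @return A data.frame with logical columns `unusual_5p`, `unusual_3p`.
#' @export
splice_dialect <- function(sequence) {
  check_nonempty(sequence)
  n <- nchar(sequence)
  if (any(n < 4L)) stop("splice_dialect requires intron length >= 4")
  data.frame(
    unusual_5p = substr(sequence, 1L, 2L) != "GT",
    unusual_3p = substr(sequence, n - 1L, n) != "AG")
}

#' CpG-island detection criteria
#'
#' Defaults follow the Takai-Jones sliding-window criteria: a 200-bp window,
#' GC fraction >= 0.55, observed/expected CpG >= 0.65, minimum reported island
#' length 500 bp, and islands separated by less than 100 bp merged.
#'
#' @param min_gc Minimum GC fraction.
#' @param min_obs_exp Minimum observed/expected CpG ratio, with expected
#'   CpG = (#C * #G) / window length.
#' @param min_length Minimum island length to report (bp).
#' @param window Sliding window size (bp).
#' @param merge_gap Islands closer than this many bp are merged.
#' @return A list of class `cpg_criteria`.
#' @export
cpg_criteria <- function(min_gc = 0.55, min_obs_exp = 0.65,
                         min_length = 500L, window = 200L,
                         merge_gap = 100L) {
  stopifnot(min_gc > 0, min_gc < 1, min_obs_exp > 0,
            min_length >= window, window >= 2L)
  structure(list(min_gc = min_gc, min_obs_exp = min_obs_exp,
                 min_length = as.integer(min_length),
                 window = as.integer(window),
                 merge_gap = as.integer(merge_gap)),
            class = "cpg_criteria")
}

# Interval-level criteria check from cumulative counts.
# cum_* are 0-prefixed cumulative counts; interval [a, b] 1-based inclusive.
interval_meets <- function(a, b, cum_c, cum_g, cum_cg, criteria) {
  len <- b - a + 1
  nc <- cum_c[b + 1L] - cum_c[a]
  ng <- cum_g[b + 1L] - cum_g[a]
  # CG dinucleotide starts within [a, b-1]
  ncg <- if (b > a) cum_cg[b] - cum_cg[a] else 0
  gc_ok <- (nc + ng) / len >= criteria$min_gc
  expc <- nc * ng / len
  oe_ok <- if (expc > 0) ncg / expc >= criteria$min_obs_exp else FALSE
  gc_ok && oe_ok
}

#' Find CpG islands with the Takai-Jones sliding-window procedure
#'
#' Slides a window of `criteria$window` bp along the sequence; a window
#' qualifies when its GC fraction and observed/expected CpG ratio meet the
#' criteria. Maximal runs of qualifying windows form candidate islands,
#' candidates closer than `merge_gap` bp are merged, each merged candidate is
#' trimmed one base at a time (alternately from the 5' and 3' end) until the
#' whole interval meets the criteria, and islands shorter than `min_length`
#' are dropped.
#'
#' @param sequence A single DNA sequence (character scalar).
#' @param criteria A [cpg_criteria()] object.
#' @return A data.frame with 1-based inclusive columns `start`, `end`, sorted
#'   and disjoint. A sequence shorter than the window returns zero rows.
#' @export
find_cpg_islands <- function(sequence, criteria = cpg_criteria()) {
  stopifnot(length(sequence) == 1L)
  check_nonempty(sequence)
  L <- nchar(sequence)
  w <- criteria$window
  empty <- data.frame(start = integer(), end = integer())
  if (L < w) return(empty)

  bases <- strsplit(sequence, "", fixed = TRUE)[[1]]
  is_c <- bases == "C"
  is_g <- bases == "G"
  is_cg <- c(is_c[-L] & is_g[-1], FALSE)  # CG dinucleotide start positions
  cum_c <- c(0, cumsum(is_c))
  cum_g <- c(0, cumsum(is_g))
  cum_cg <- c(0, cumsum(is_cg))

  starts <- seq_len(L - w + 1L)
  nc <- cum_c[starts + w] - cum_c[starts]
  ng <- cum_g[starts + w] - cum_g[starts]
  ncg <- cum_cg[starts + w - 1L] - cum_cg[starts]
  expc <- nc * ng / w
  qualifying <- (nc + ng) / w >= criteria$min_gc &
    expc > 0 & ncg / expc >= criteria$min_obs_exp
  if (!any(qualifying)) return(empty)

  # maximal runs of qualifying window starts -> covered base intervals
  r <- rle(qualifying)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  ok <- r$values
  cand <- data.frame(start = run_start[ok], end = run_end[ok] + w - 1L)

  # merge candidates separated by less than merge_gap bases
  merged_start <- integer(); merged_end <- integer()
  cs <- cand$start[1]; ce <- cand$end[1]
  for (i in seq_len(nrow(cand))[-1]) {
    if (cand$start[i] - ce - 1L < criteria$merge_gap) {
      ce <- max(ce, cand$end[i])
    } else {
      merged_start <- c(merged_start, cs); merged_end <- c(merged_end, ce)
      cs <- cand$start[i]; ce <- cand$end[i]
    }
  }
  merged_start <- c(merged_start, cs); merged_end <- c(merged_end, ce)

  # trim each merged candidate until the whole interval meets the criteria
  out_start <- integer(); out_end <- integer()
  for (i in seq_along(merged_start)) {
    a <- merged_start[i]; b <- merged_end[i]
    from_5p <- TRUE
    while (b - a + 1L >= criteria$min_length &&
           !interval_meets(a, b, cum_c, cum_g, cum_cg, criteria)) {
      if (from_5p) a <- a + 1L else b <- b - 1L
      from_5p <- !from_5p
    }
    if (b - a + 1L >= criteria$min_length) {
      out_start <- c(out_start, a); out_end <- c(out_end, b)
    }
  }
  data.frame(start = out_start, end = out_end)
}

#' Does an intron contain a CpG island?
#'
#' @inheritParams find_cpg_islands
#' @return TRUE iff [find_cpg_islands()] reports at least one island.
#' @export
cpg_island_present <- function(sequence, criteria = cpg_criteria()) {
  nrow(find_cpg_islands(sequence, criteria)) > 0L
}

#' Per-intron feature table
#'
#' Computes, for every intron row, its length, ordinal, GC-motif density, GC
#' content, GC content excluding motifs, splice-site dialect flags and
#' (optionally) CpG-island presence.
#'
#' @param introns A per-intron data.frame with at least `sequence` and
#'   `ordinal` columns (see [introns_table()]).
#' @param motif GC motif string (default "GC").
#' @param criteria A [cpg_criteria()] object.
#' @param include_cpg Compute the CpG-island column (linear in total sequence
#'   length; switch off when only GC/splice features are needed).
#' @return The input with columns `gc_density`, `gc_content`, `gc_excl`,
#'   `unusual_5p`, `unusual_3p` and (if requested) `cpg_present` appended.
#' @export
intron_feature_table <- function(introns, motif = "GC",
                                 criteria = cpg_criteria(),
                                 include_cpg = TRUE) {
  stopifnot(is.data.frame(introns), nrow(introns) > 0L,
            all(c("sequence", "ordinal") %in% names(introns)))
  out <- introns
  out$gc_density <- gc_motif_density(introns$sequence, motif)
  out$gc_content <- gc_content(introns$sequence)
  out$gc_excl <- out$gc_content - nchar(motif) * out$gc_density
  dial <- splice_dialect(introns$sequence)
  out$unusual_5p <- dial$unusual_5p
  out$unusual_3p <- dial$unusual_3p
  if (include_cpg) {
    out$cpg_present <- vapply(introns$sequence, cpg_island_present,
                              logical(1), criteria = criteria,
                              USE.NAMES = FALSE)
  }
  out
}

#' The seven-entry per-gene feature vector
#'
#' Average intron size, number of introns, total intronic bp, GC-motif density
#' of the first intron and mean over later introns, and GC content excluding
#' motifs of the first intron and mean over later introns. Later-intron
#' entries are unweighted means over introns with ordinal >= 2 and are NA
#' (flagged missing) for single-intron genes.
#'
#' @param gene A `gene_record` with at least one intron.
#' @param motif GC motif string.
#' @return A one-row data.frame with columns `gene_id`, `avg_intron_size`,
#'   `n_introns`, `total_intronic_bp`, `gc_density_first`, `gc_density_later`,
#'   `gc_excl_first`, `gc_excl_later`.
#' @export
gene_feature_vector <- function(gene, motif = "GC") {
  stopifnot(inherits(gene, "gene_record"))
  if (nrow(gene$introns) == 0L) {
    stop("gene ", gene$gene_id, " has no introns")
  }
  tab <- cbind(gene$introns,
               gene_id = gene$gene_id, stringsAsFactors = FALSE)
  gene_feature_table(tab, motif = motif)
}

#' Per-gene feature table for a whole corpus
#'
#' Vectorised form of [gene_feature_vector()] over a flat per-intron table.
#'
#' @param introns Per-intron data.frame with `gene_id`, `ordinal`, `sequence`,
#'   `length` columns.
#' @param motif GC motif string.
#' @return One row per gene with the seven features (later-intron fields NA
#'   for single-intron genes), plus label columns when present in the input.
#' @export
gene_feature_table <- function(introns, motif = "GC") {
  stopifnot(nrow(introns) > 0L)
  dens <- gc_motif_density(introns$sequence, motif)
  excl <- gc_content(introns$sequence) - nchar(motif) * dens
  first <- introns$ordinal == 1L
  gid <- introns$gene_id

  agg <- function(x, ids, f) {
    v <- tapply(x, ids, f)
    v[match(unique(gid), names(v))]
  }
  genes <- unique(gid)
  later <- !first
  later_mean <- function(x) {
    v <- rep(NA_real_, length(genes))
    if (any(later)) {
      m <- tapply(x[later], gid[later], mean)
      v[match(names(m), genes)] <- as.numeric(m)
    }
    v
  }
  fi <- match(genes, gid[first])
  out <- data.frame(
    gene_id = genes,
    avg_intron_size = as.numeric(agg(introns$length, gid, mean)),
    n_introns = as.integer(agg(introns$ordinal, gid, length)),
    total_intronic_bp = as.numeric(agg(introns$length, gid, sum)),
    gc_density_first = dens[first][fi],
    gc_density_later = later_mean(dens),
    gc_excl_first = excl[first][fi],
    gc_excl_later = later_mean(excl),
    stringsAsFactors = FALSE)
  for (col in c("category", "binary", "essential_fraction")) {
    if (col %in% names(introns)) {
      out[[col]] <- introns[[col]][match(genes, gid)]
    }
  }
  rownames(out) <- NULL
  out
}

check_nonempty <- function(sequence) {
  if (length(sequence) == 0L || any(!nzchar(sequence)) || anyNA(sequence)) {
    stop("empty sequence")
  }
  invisible(TRUE)
}
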