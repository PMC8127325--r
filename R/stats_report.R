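# Group-comparison statistics and figure-style summary tables: six-group
# (class x first/later) summaries of intron length, GC density, GC content
# excluding motifs, unusual-splice and CpG-presence proportions, gene-level
# intron count and total intronic bp, with pairwise rank tests.

#' Two-sample rank test (Mann-Whitney U)
#'
#' For small samples (n_a + n_b <= 12) the two-sided p-value is computed by
#' exact enumeration of all label assignments (valid under ties); larger
#' samples use the tie-corrected normal approximation.
#'
#' @param sample_a,sample_b Non-empty numeric vectors.
#' @return A list with `U` (the U statistic of `sample_a`) and `p`
#'   (two-sided).
#' @export
rank_test <- function(sample_a, sample_b) {
  stopifnot(length(sample_a) >= 1L, length(sample_b) >= 1L)
  na <- length(sample_a); nb <- length(sample_b)
  r <- rank(c(sample_a, sample_b))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  if (na + nb <= 12L) {
    # exact permutation distribution of U over all label assignments
    pooled <- c(sample_a, sample_b)
    rr <- rank(pooled)
    combs <- utils::combn(na + nb, na)
    stats_all <- apply(combs, 2, function(idx)
      sum(rr[idx]) - na * (na + 1) / 2)
    mu <- na * nb / 2
    p <- mean(abs(stats_all - mu) >= abs(U - mu) - 1e-9)
  } else {
    p <- stats::wilcox.test(sample_a, sample_b, exact = FALSE,
                            correct = FALSE)$p.value
  }
  list(U = U, p = p)
}

#' Gaussian-asymptotic notch interval around the median
#'
#' The conventional notched-boxplot confidence interval,
#' median +/- 1.57 * IQR / sqrt(n).
#'
#' @param sample Numeric vector.
#' @return Named numeric vector `c(low, high)`.
#' @export
notch_interval <- function(sample) {
  stopifnot(length(sample) >= 1L)
  m <- stats::median(sample)
  iqr <- stats::IQR(sample)
  half <- 1.57 * iqr / sqrt(length(sample))
  c(low = m - half, high = m + half)
}

group_summary <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  nt <- notch_interval(x)
  data.frame(n = length(x), mean = mean(x), q1 = q[1], median = q[2],
             q3 = q[3], notch_low = nt["low"], notch_high = nt["high"],
             row.names = NULL)
}

#' Figure-style report tables for a corpus
#'
#' Builds six-group (essential/conditional/nonessential x first/later)
#' summaries for intron length, GC-motif density and GC content excluding
#' motifs; proportion summaries for unusual 5'/3' splice sites and (when
#' present) CpG-island presence; gene-level summaries of intron count and
#' total intronic bp; and all pairwise rank tests within each panel. Empty
#' groups are marked absent rather than failing.
#'
#' @param intron_features Per-intron feature table from
#'   [intron_feature_table()] with a `category` column.
#' @param gene_features Per-gene feature table from [gene_feature_table()]
#'   with a `category` column.
#' @return A list with `groups` (summary table), `proportions`, `gene_level`
#'   and `tests` (pairwise rank tests) data.frames.
#' @export
build_report <- function(intron_features, gene_features) {
  stopifnot("category" %in% names(intron_features),
            "category" %in% names(gene_features))
  classes <- c("essential", "conditional", "nonessential")
  pos <- ifelse(intron_features$ordinal == 1L, "first", "later")
  grp <- interaction(intron_features$category, pos, sep = ".")

  metrics <- c(length = "length", gc_density = "gc_density",
               gc_excl = "gc_excl")
  groups <- list(); tests <- list(); props <- list()
  for (mname in names(metrics)) {
    col <- metrics[[mname]]
    for (cls in classes) for (p in c("first", "later")) {
      x <- intron_features[[col]][intron_features$category == cls & pos == p]
      if (length(x) == 0L) {
        groups[[length(groups) + 1L]] <- data.frame(
          metric = mname, group = paste(cls, p, sep = "."), n = 0L,
          mean = NA, q1 = NA, median = NA, q3 = NA,
          notch_low = NA, notch_high = NA)
      } else {
        groups[[length(groups) + 1L]] <- cbind(
          data.frame(metric = mname, group = paste(cls, p, sep = ".")),
          group_summary(x))
      }
    }
    # pairwise tests over the six groups
    lv <- levels(grp)
    for (i in seq_along(lv)) for (j in seq_along(lv)) {
      if (j <= i) next
      xa <- intron_features[[col]][grp == lv[i]]
      xb <- intron_features[[col]][grp == lv[j]]
      if (length(xa) && length(xb)) {
        rt <- rank_test(xa, xb)
        tests[[length(tests) + 1L]] <- data.frame(
          metric = mname, group_a = lv[i], group_b = lv[j],
          U = rt$U, p = rt$p)
      }
    }
  }

  flag_cols <- intersect(c("unusual_5p", "unusual_3p", "cpg_present"),
                         names(intron_features))
  for (col in flag_cols) {
    for (cls in classes) for (p in c("first", "later")) {
      x <- intron_features[[col]][intron_features$category == cls & pos == p]
      props[[length(props) + 1L]] <- data.frame(
        flag = col, group = paste(cls, p, sep = "."),
        n = length(x),
        proportion = if (length(x)) mean(x) else NA_real_)
    }
  }

  gene_level <- list()
  for (col in c("n_introns", "total_intronic_bp")) {
    for (cls in classes) {
      x <- gene_features[[col]][gene_features$category == cls]
      if (length(x)) {
        gene_level[[length(gene_level) + 1L]] <- cbind(
          data.frame(metric = col, group = cls), group_summary(x))
      }
    }
    for (i in seq_along(classes)) for (j in seq_along(classes)) {
      if (j <= i) next
      xa <- gene_features[[col]][gene_features$category == classes[i]]
      xb <- gene_features[[col]][gene_features$category == classes[j]]
      if (length(xa) && length(xb)) {
        rt <- rank_test(xa, xb)
        tests[[length(tests) + 1L]] <- data.frame(
          metric = col, group_a = classes[i], group_b = classes[j],
          U = rt$U, p = rt$p)
      }
    }
  }

  list(groups = do.call(rbind, groups),
       proportions = do.call(rbind, props),
       gene_level = do.call(rbind, gene_level),
       tests = do.call(rbind, tests))
}
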