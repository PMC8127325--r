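# Independent brute-force oracles. These deliberately avoid the code paths of
# the package implementation (Biostrings pattern counting, cumulative sums,
# grouped threshold sweeps) and recompute everything by naive scanning.

# overlapping motif occurrences by position-by-position substring comparison
oracle_motif_count <- function(sequence, motif = "GC") {
  L <- nchar(sequence)
  m <- nchar(motif)
  if (L < m) return(0L)
  hits <- 0L
  for (i in seq_len(L - m + 1L)) {
    if (substr(sequence, i, i + m - 1L) == motif) hits <- hits + 1L
  }
  hits
}

oracle_gc_content <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  sum(chars == "G" | chars == "C") / length(chars)
}

oracle_splice <- function(sequence) {
  L <- nchar(sequence)
  c(unusual_5p = substr(sequence, 1, 2) != "GT",
    unusual_3p = substr(sequence, L - 1, L) != "AG")
}

# Takai-Jones islands recomputed naively: per-window counts by elementwise
# sums over the character vector, runs/merging/trimming by explicit loops.
oracle_cpg_islands <- function(sequence, criteria = IntronEss::cpg_criteria()) {
  L <- nchar(sequence)
  w <- criteria$window
  if (L < w) return(data.frame(start = integer(), end = integer()))
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  meets <- function(a, b) {
    sub <- chars[a:b]
    len <- b - a + 1
    nc <- sum(sub == "C"); ng <- sum(sub == "G")
    ncg <- sum(sub[-length(sub)] == "C" & sub[-1] == "G")
    ex <- nc * ng / len
    (nc + ng) / len >= criteria$min_gc &&
      ex > 0 && ncg / ex >= criteria$min_obs_exp
  }
  ok <- vapply(seq_len(L - w + 1L), function(i) meets(i, i + w - 1L),
               logical(1))
  # runs of qualifying starts
  cand <- list()
  i <- 1L
  while (i <= length(ok)) {
    if (ok[i]) {
      j <- i
      while (j < length(ok) && ok[j + 1L]) j <- j + 1L
      cand[[length(cand) + 1L]] <- c(i, j + w - 1L)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(cand)) return(data.frame(start = integer(), end = integer()))
  # merge gaps < merge_gap
  merged <- list(cand[[1]])
  for (k in seq_along(cand)[-1]) {
    prev <- merged[[length(merged)]]
    if (cand[[k]][1] - prev[2] - 1L < criteria$merge_gap) {
      merged[[length(merged)]] <- c(prev[1], max(prev[2], cand[[k]][2]))
    } else merged[[length(merged) + 1L]] <- cand[[k]]
  }
  # alternate 5'/3' trim until the whole interval qualifies
  out <- data.frame(start = integer(), end = integer())
  for (iv in merged) {
    a <- iv[1]; b <- iv[2]; from5 <- TRUE
    while (b - a + 1L >= criteria$min_length && !meets(a, b)) {
      if (from5) a <- a + 1L else b <- b - 1L
      from5 <- !from5
    }
    if (b - a + 1L >= criteria$min_length) {
      out <- rbind(out, data.frame(start = a, end = b))
    }
  }
  out
}

# AUC as the Mann-Whitney statistic by exhaustive pair counting, ties half
oracle_auc <- function(scores, labels, positive = "essential") {
  pos <- which(labels == positive)
  neg <- which(labels != positive)
  total <- 0
  for (i in pos) for (j in neg) {
    total <- total + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  total / (length(pos) * length(neg))
}

# two-sided permutation p-value of the rank-sum by full enumeration
oracle_rank_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  r <- rank(pooled)
  obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * length(b) / 2
  combs <- utils::combn(length(pooled), na)
  stats_all <- apply(combs, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  mean(abs(stats_all - mu) >= abs(obs - mu) - 1e-9)
}

random_dna <- function(n, gc = 0.45) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
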