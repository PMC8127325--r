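# Gene-level aggregation of intron essentiality scores, and ROC/AUC
# evaluation. A gene's majority score is the mean of its introns' scores
# from one model; the double classifier pools the intron scores from the
# first-window and last-window models.

#' Majority gene score
#'
#' The gene's essentiality score is the arithmetic mean of the essentiality
#' scores of its introns under one model.
#'
#' @param scores Numeric vector of intron scores for one gene (length >= 1).
#' @return The mean score.
#' @export
majority_gene_score <- function(scores) {
  stopifnot(length(scores) >= 1L, all(is.finite(scores)))
  mean(scores)
}

#' Double-classifier gene score
#'
#' Pools the intron scores of a gene from the first-window and last-window
#' models and returns their mean. Because both models score the same introns,
#' this equals the average of the two per-model majority scores.
#'
#' @param first_scores,last_scores Numeric vectors of the gene's intron
#'   scores under the first-window and last-window models.
#' @return The pooled mean score.
#' @export
double_gene_score <- function(first_scores, last_scores) {
  stopifnot(length(first_scores) >= 1L,
            length(first_scores) == length(last_scores))
  mean(c(first_scores, last_scores))
}

#' Build a per-intron score table
#'
#' @param gene_id,ordinal Identifiers of each scored intron.
#' @param model_kind "first" or "last" for each row.
#' @param score Essentiality scores in \[0, 1\].
#' @return A validated data.frame of class `score_table`.
#' @export
score_table <- function(gene_id, ordinal, model_kind, score) {
  stopifnot(all(model_kind %in% c("first", "last")),
            all(is.finite(score)), all(score >= 0), all(score <= 1))
  tab <- data.frame(gene_id = gene_id, ordinal = ordinal,
                    model_kind = model_kind, score = score,
                    stringsAsFactors = FALSE)
  if (anyDuplicated(tab[, c("gene_id", "ordinal", "model_kind")])) {
    stop("duplicate (gene, ordinal, model_kind) rows in score table")
  }
  structure(tab, class = c("score_table", "data.frame"))
}

#' ROC curve and trapezoidal AUC
#'
#' Sweeps a threshold over the unique scores (ties grouped, which is
#' equivalent to half-credit in the Mann-Whitney formulation) and integrates
#' the ROC curve by the trapezoid rule.
#'
#' @param scores Numeric scores, higher = more essential.
#' @param labels Binary labels parallel to `scores`.
#' @param positive The label counted as positive (default "essential").
#' @return A list of class `roc_result` with `thresholds`, `fpr`, `tpr`
#'   (nondecreasing from (0,0) to (1,1)) and `auc`.
#' @export
roc_auc <- function(scores, labels, positive = "essential") {
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  pos <- labels == positive
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) {
    stop("roc_auc requires both classes present")
  }
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; p <- pos[o]
  # group tied scores
  last_of_group <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(p)[last_of_group]
  fp <- cumsum(!p)[last_of_group]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(thresholds = c(Inf, s[last_of_group]),
                 fpr = fpr, tpr = tpr, auc = auc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%d thresholds)\n",
              x$auc, length(x$thresholds)))
  invisible(x)
}

#' Gene-level majority scores from a score table
#'
#' @param tab A `score_table` (single model kind, or filtered by caller).
#' @return A data.frame with one row per gene: `gene_id`, `score`.
#' @export
gene_scores <- function(tab) {
  m <- tapply(tab$score, tab$gene_id, mean)
  data.frame(gene_id = names(m), score = as.numeric(m),
             stringsAsFactors = FALSE)
}

#' AUC report across intron- and gene-level classifiers
#'
#' Reproduces the evaluation panel of the intron essentiality study: intron-
#' level AUC of the first-window and last-window models, their gene-level
#' majority classifiers, the double majority classifier, and the first-intron
#' panel (each model on first introns only, plus their dual average).
#'
#' @param first_tab,last_tab `score_table`s from the first-window and
#'   last-window models over the same introns.
#' @param labels Data.frame with `gene_id` and `binary` columns giving the
#'   gene-level label.
#' @return A data.frame with columns `measure`, `level`, `auc`, `n`.
#' @export
evaluate_suite <- function(first_tab, last_tab, labels) {
  lab_of <- function(ids) labels$binary[match(ids, labels$gene_id)]
  rows <- list()
  add <- function(measure, level, scores, labs) {
    rows[[length(rows) + 1L]] <<- data.frame(
      measure = measure, level = level,
      auc = roc_auc(scores, labs)$auc, n = length(scores),
      stringsAsFactors = FALSE)
  }
  # intron level
  add("intron_first_model", "intron", first_tab$score, lab_of(first_tab$gene_id))
  add("intron_last_model", "intron", last_tab$score, lab_of(last_tab$gene_id))
  # gene-level majority classifiers
  gf <- gene_scores(first_tab)
  gl <- gene_scores(last_tab)
  add("majority_first_model", "gene", gf$score, lab_of(gf$gene_id))
  add("majority_last_model", "gene", gl$score, lab_of(gl$gene_id))
  # double majority classifier (pooled intron scores from both models)
  both <- rbind(as.data.frame(first_tab), as.data.frame(last_tab))
  gd <- gene_scores(both)
  add("double_classifier", "gene", gd$score, lab_of(gd$gene_id))
  # first-intron panel
  f1 <- first_tab[first_tab$ordinal == 1L, , drop = FALSE]
  l1 <- last_tab[last_tab$ordinal == 1L, , drop = FALSE]
  add("first_intron_first_model", "first_intron", f1$score, lab_of(f1$gene_id))
  add("first_intron_last_model", "first_intron", l1$score, lab_of(l1$gene_id))
  m <- match(paste(f1$gene_id, f1$ordinal), paste(l1$gene_id, l1$ordinal))
  dual <- (f1$score + l1$score[m]) / 2
  add("first_intron_dual", "first_intron", dual, lab_of(f1$gene_id))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
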