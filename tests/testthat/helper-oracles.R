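# Independent oracles used to validate the metric implementations.
# These deliberately avoid the contingency-table formulas in R/metrics.R:
# everything is computed by direct enumeration over cell pairs or by
# direct entropy/mutual-information evaluation.

# All set partitions of n elements as restricted-growth strings.
all_partitions <- function(n) {
  out <- list()
  recurse <- function(prefix, max_used) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (v in seq_len(max_used + 1L)) {
      recurse(c(prefix, v), max(max_used, v))
    }
  }
  recurse(integer(0), 0L)
  out
}

# Pair-level confusion counts between two partitions.
pair_counts <- function(u, v) {
  n <- length(u)
  su <- outer(u, u, "==")[upper.tri(diag(n))]
  sv <- outer(v, v, "==")[upper.tri(diag(n))]
  list(
    n11 = sum(su & sv),    # together in both
    n10 = sum(su & !sv),   # together in truth only
    n01 = sum(!su & sv),   # together in prediction only
    n00 = sum(!su & !sv)
  )
}

oracle_ari <- function(u, v) {
  p <- pair_counts(u, v)
  den <- (p$n11 + p$n10) * (p$n10 + p$n00) + (p$n11 + p$n01) * (p$n01 + p$n00)
  if (den == 0) {
    total <- p$n11 + p$n10 + p$n01 + p$n00
    return(if (p$n11 + p$n00 == total) 1 else 0)
  }
  2 * (p$n11 * p$n00 - p$n10 * p$n01) / den
}

oracle_fmi <- function(u, v) {
  p <- pair_counts(u, v)
  if (p$n11 == 0) return(0)
  p$n11 / sqrt((p$n11 + p$n01) * (p$n11 + p$n10))
}

# V-measure via mutual information (different algebra from the
# conditional-entropy route used by the implementation).
oracle_v_measure <- function(u, v) {
  n <- length(u)
  pu <- table(u) / n
  pv <- table(v) / n
  h_u <- -sum(pu * log(pu))
  h_v <- -sum(pv * log(pv))
  mi <- 0
  for (a in names(pu)) {
    for (b in names(pv)) {
      pab <- sum(u == a & v == b) / n
      if (pab > 0) mi <- mi + pab * log(pab / (pu[[a]] * pv[[b]]))
    }
  }
  hom <- if (h_u == 0) 1 else mi / h_u
  com <- if (h_v == 0) 1 else mi / h_v
  if (hom + com == 0) 0 else 2 * hom * com / (hom + com)
}

# Weighted F-score by direct per-class counting over the label vectors
# (identity mapping: assumes prediction uses the true class names).
oracle_f_score <- function(truth, pred) {
  classes <- unique(truth)
  n <- length(truth)
  total <- 0
  for (cls in classes) {
    tp <- sum(truth == cls & pred == cls)
    prec <- if (sum(pred == cls) > 0) tp / sum(pred == cls) else 0
    rec <- tp / sum(truth == cls)
    f_i <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    total <- total + sum(truth == cls) / n * f_i
  }
  total
}

# ROC area by exhaustive positive/negative pair counting, ties one half.
oracle_auc <- function(scores, truth) {
  pos <- scores[truth]
  neg <- scores[!truth]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Best-case membership agreement between a clustering and ground truth
# under greedy optimal matching of cluster ids to classes.
matched_agreement <- function(truth, cluster) {
  tab <- table(truth, cluster)
  agreement <- 0
  while (nrow(tab) > 0 && ncol(tab) > 0) {
    ix <- which(tab == max(tab), arr.ind = TRUE)[1, ]
    agreement <- agreement + tab[ix[1], ix[2]]
    tab <- tab[-ix[1], -ix[2], drop = FALSE]
  }
  agreement / length(truth)
}
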