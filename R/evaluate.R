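#' Area under the ROC curve
#'
#' Mann--Whitney formulation: the probability that a randomly chosen
#' positive cell outscores a randomly chosen negative cell, ties counted
#' as one half. Computed from midranks, which is exactly the trapezoidal
#' ROC area.
#'
#' @param score numeric score per cell (higher = more senescent).
#' @param truth binary ground truth (0/1 or logical); both classes must be
#'   present.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(score, truth) {
  truth <- as.integer(as.logical(truth))
  if (length(score) != length(truth)) stopf("score and truth misaligned")
  n1 <- sum(truth == 1L); n0 <- sum(truth == 0L)
  if (n1 == 0L || n0 == 0L) stopf("both classes must be present")
  r <- rank(score)                       # midranks handle ties as 1/2
  (sum(r[truth == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Accuracy and F1 of binary senescence calls
#'
#' `accuracy = (TP + TN) / n`; `F1 = 2 P R / (P + R)` with precision
#' `P = TP / (TP + FP)` and recall `R = TP / (TP + FN)`, and `F1 = 0`
#' when `P + R` is undefined or zero.
#'
#' @param pred predicted binary labels (logical or 0/1).
#' @param truth true binary labels.
#' @return one-row tibble with `accuracy`, `f1`, `tp`, `fp`, `fn`, `tn`.
#' @export
accuracy_f1 <- function(pred, truth) {
  pred <- as.logical(pred); truth <- as.logical(truth)
  if (length(pred) != length(truth)) stopf("pred and truth misaligned")
  tp <- sum(pred & truth); fp <- sum(pred & !truth)
  fn <- sum(!pred & truth); tn <- sum(!pred & !truth)
  acc <- (tp + tn) / length(pred)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  tibble::tibble(accuracy = acc, f1 = f1, tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Old/young enrichment among top-scoring cells
#'
#' Cells are ranked by score; the top `ceiling(top_frac * n)` (stable
#' order at ties) form the top quantile. With `a`/`b` the old/young
#' counts in the top quantile and `c`/`d` in the remainder, the
#' enrichment is `(a/(a+b)) / (c/(c+d))` — how over-represented the old
#' group is among the highest-scoring cells. Invariant to strictly
#' monotone transforms of the score.
#'
#' @param score numeric score per cell.
#' @param group factor/character per cell with exactly two levels.
#' @param old which `group` level is the "old" group (default: the
#'   lexicographically larger level).
#' @param top_frac fraction of cells in the top quantile (default 0.01).
#' @return positive enrichment ratio.
#' @export
snc_enrichment <- function(score, group, old = NULL, top_frac = 0.01) {
  group <- as.character(group)
  lev <- sort(unique(group))
  if (length(lev) != 2L) stopf("`group` must have exactly two levels")
  old <- old %||% lev[2]
  if (!old %in% lev) stopf("`old` level %s not found", old)
  n <- length(score)
  n_top <- ceiling(top_frac * n)
  if (n_top < 1L || n_top >= n) stopf("top_frac yields a degenerate split")
  top <- order(-score)[seq_len(n_top)]   # stable order breaks score ties
  is_old <- group == old
  a <- sum(is_old[top]); b <- n_top - a
  c_ <- sum(is_old[-top]); d <- (n - n_top) - c_
  if (a + b == 0L || c_ + d == 0L) stopf("empty stratum")
  (a / (a + b)) / (c_ / (c_ + d))
}

#' Simulate a targeted spatial panel
#'
#' Emulates building an in-situ panel (e.g. a 10x Xenium panel of a few
#' hundred genes) that lacks senescence genes, expanded with `n_add`
#' randomly chosen signature genes, then subsetting a count matrix to the
#' expanded panel.
#'
#' @param counts genes x cells count matrix.
#' @param base_panel [gene_set()] (or character vector): the base panel.
#' @param signature [gene_set()] (or character vector): the senescence
#'   signature to sample additions from.
#' @param n_add number of signature genes to add (sampled from those not
#'   already on the panel).
#' @param seed RNG seed for the sampling.
#' @return the count matrix subsetted to the expanded panel genes present
#'   in the data.
#' @export
simulate_xenium_panel <- function(counts, base_panel, signature, n_add,
                                  seed = 1L) {
  counts <- assert_count_matrix(counts)
  base <- if (inherits(base_panel, "gene_set")) base_panel$genes else as.character(base_panel)
  sig <- if (inherits(signature, "gene_set")) signature$genes else as.character(signature)
  pool <- setdiff(sig, base)
  if (n_add > length(pool))
    stopf("n_add = %d exceeds the %d signature genes off the panel",
          n_add, length(pool))
  set.seed(seed)
  add <- if (n_add > 0) sample(pool, n_add) else character(0)
  panel <- union(base, add)
  keep <- intersect(rownames(counts), panel)
  if (!length(keep)) stopf("expanded panel shares no genes with the data")
  counts[keep, , drop = FALSE]
}
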