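#' Identify the senescence-capturing bottleneck neuron
#'
#' The roles of the two bottleneck neurons are undetermined during
#' training, so the senescence axis is found post hoc: for each neuron,
#' the absolute Pearson correlation between its (tanh-activated) values
#' and every signature gene row of X' is averaged over genes; the neuron
#' with the larger mean wins. A constant neuron contributes correlation 0
#' for every gene; an exact tie selects neuron 1.
#'
#' @param fit a `sen_fit` from [sen_train()].
#' @param Xp the `scaled_matrix` the model was fitted on (or any matrix on
#'   the same genes).
#' @param genes optional character vector restricting the signature genes
#'   used (default: all rows of `Xp`).
#' @return list with `neuron` (1 or 2) and `mean_abs_cor` (length-2).
#' @export
select_senescence_neuron <- function(fit, Xp, genes = NULL) {
  stopifnot(inherits(fit, "sen_fit"))
  v <- if (inherits(Xp, "scaled_matrix")) Xp$values else Xp
  use <- if (is.null(genes)) rownames(v) else intersect(genes, rownames(v))
  if (!length(use)) stopf("no signature genes available for neuron selection")
  B <- model_forward(fit, Xp)$B
  mac <- vapply(1:2, function(k) {
    mean(vapply(use, function(g) abs(safe_cor(B[, k], v[g, ])), numeric(1)))
  }, numeric(1))
  list(neuron = which.max(mac), mean_abs_cor = mac)
}

#' Anchor the score sign to a canonical senescence marker
#'
#' A bottleneck axis has arbitrary sign, so the score is correlated with
#' the expression of an anchor gene (CDKN1A/p21 by default); a negative
#' correlation flips every score. If the anchor is absent or constant the
#' scores are returned unchanged with a warning.
#'
#' @param scores a `sen_scores` tibble from [score_cells()] (or a numeric
#'   vector).
#' @param Xp expression matrix used for the anchor correlation, genes x
#'   cells (the standardized X' by convention).
#' @param anchor anchor gene symbol (default `"CDKN1A"`).
#' @return the scores with sign fixed; attribute `flipped` records whether
#'   a flip occurred. Orientation is idempotent.
#' @export
orient_scores <- function(scores, Xp, anchor = "CDKN1A") {
  v <- if (inherits(Xp, "scaled_matrix")) Xp$values else Xp
  sc <- if (is.data.frame(scores)) scores$score else as.numeric(scores)
  flipped <- FALSE
  if (!anchor %in% rownames(v)) {
    warnf("anchor gene %s not present; scores left unoriented", anchor)
  } else {
    r <- safe_cor(sc, v[anchor, ])
    if (r == 0 && stats::sd(v[anchor, ]) == 0)
      warnf("anchor gene %s is constant; scores left unoriented", anchor)
    if (r < 0) { sc <- -sc; flipped <- TRUE }
  }
  if (is.data.frame(scores)) {
    scores$score <- sc
    attr(scores, "flipped") <- isTRUE(attr(scores, "flipped")) != flipped  # xor
    attr(scores, "anchor") <- anchor
    scores
  } else {
    structure(sc, flipped = flipped, anchor = anchor)
  }
}

#' Continuous senescence scores for all cells
#'
#' The final score of a cell is the tanh-activated value of the
#' senescence-capturing bottleneck neuron, sign-anchored so that higher
#' scores mean more senescent. Every cell is scored, including
#' validation-split cells.
#'
#' @param fit a `sen_fit` from [sen_train()].
#' @param Xp the `scaled_matrix` the model was fitted on.
#' @param anchor sign-anchor gene (default `"CDKN1A"`).
#' @return a `sen_scores` tibble with columns `cell_id`, `score`
#'   (in (-1, 1)); attributes `neuron_index`, `mean_abs_cor`, `flipped`,
#'   `anchor`.
#' @export
score_cells <- function(fit, Xp, anchor = "CDKN1A") {
  stopifnot(inherits(fit, "sen_fit"))
  sel <- select_senescence_neuron(fit, Xp)
  B <- model_forward(fit, Xp)$B
  v <- if (inherits(Xp, "scaled_matrix")) Xp$values else Xp
  out <- tibble::tibble(cell_id = colnames(v),
                        score = unname(B[, sel$neuron]))
  attr(out, "neuron_index") <- sel$neuron
  attr(out, "mean_abs_cor") <- sel$mean_abs_cor
  attr(out, "flipped") <- FALSE
  class(out) <- c("sen_scores", class(out))
  orient_scores(out, Xp, anchor = anchor)
}

#' Single-marker baseline score
#'
#' The simplest competing approach: the log-normalized expression of one
#' marker gene (e.g. CDKN1A or CDKN2A) is the continuous score, and cells
#' with positive expression are called senescent.
#'
#' @param counts genes x cells count matrix.
#' @param gene marker gene symbol.
#' @return tibble with `cell_id`, `score` (log-normalized expression) and
#'   `senescent` (`score > 0`).
#' @export
marker_score <- function(counts, gene = "CDKN1A") {
  counts <- assert_count_matrix(counts)
  if (!gene %in% rownames(counts)) stopf("gene %s not in the matrix", gene)
  ln <- normalize_log(counts)
  tibble::tibble(cell_id = colnames(counts), score = unname(ln[gene, ]),
                 senescent = unname(ln[gene, ] > 0))
}
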