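#' Permutation-null uncertainty scores
#'
#' For each of `n_perm` replicates, every cell's standardized signature
#' profile (its column of X') is shuffled across genes — destroying the
#' gene identity while keeping the cell's value multiset — and pushed
#' through the already-fitted encoder; the senescence neuron's value
#' (with the fitted orientation sign) is recomputed. A cell's uncertainty
#' is the fraction of replicates whose permuted score strictly exceeds
#' its original score, so uncertainties lie on the grid 0, 1/n_perm, ...,
#' 1.
#'
#' @param fit a `sen_fit`.
#' @param Xp the `scaled_matrix` the model was fitted on.
#' @param scores the `sen_scores` from [score_cells()].
#' @param n_perm number of permutation replicates (default 50).
#' @param seed RNG seed for the shuffles.
#' @return tibble with `cell_id`, `uncertainty`; attributes `n_perm`,
#'   `perm_seed`.
#' @export
permutation_uncertainty <- function(fit, Xp, scores, n_perm = 50L,
                                    seed = 1L) {
  stopifnot(inherits(fit, "sen_fit"), n_perm >= 1)
  v <- if (inherits(Xp, "scaled_matrix")) Xp$values else Xp
  k <- attr(scores, "neuron_index") %||% stopf("scores lack a neuron index")
  sgn <- if (isTRUE(attr(scores, "flipped"))) -1 else 1
  orig <- scores$score
  set.seed(seed)
  exceed <- numeric(ncol(v))
  for (r in seq_len(n_perm)) {
    vp <- apply(v, 2L, sample)          # independent shuffle per cell
    B <- nn_forward(t(vp), fit$params, "tanh")$B
    exceed <- exceed + unname(sgn * B[, k] > orig)
  }
  out <- tibble::tibble(cell_id = colnames(v), uncertainty = exceed / n_perm)
  attr(out, "n_perm") <- as.integer(n_perm)
  attr(out, "perm_seed") <- as.integer(seed)
  out
}

#' Senescence score cutoff from uncertainty scores
#'
#' The cutoff is the smallest observed score value `c` such that, among
#' cells with score strictly above `c`, fewer than `max_unreliable_frac`
#' have uncertainty above `unc_threshold`. If no observed value
#' qualifies, `NA` is returned, meaning no senescent cells are callable.
#'
#' @param scores `sen_scores` tibble (or numeric vector).
#' @param uncertainty output of [permutation_uncertainty()] (or numeric
#'   vector aligned with the scores).
#' @param max_unreliable_frac tolerated fraction of unreliable cells
#'   above the cutoff (default 0.01).
#' @param unc_threshold uncertainty level defining "unreliable" (default
#'   0.5).
#' @return a single score value, or `NA_real_`.
#' @export
score_cutoff <- function(scores, uncertainty, max_unreliable_frac = 0.01,
                         unc_threshold = 0.5) {
  sc <- if (is.data.frame(scores)) scores$score else as.numeric(scores)
  un <- if (is.data.frame(uncertainty)) uncertainty$uncertainty else as.numeric(uncertainty)
  if (length(sc) != length(un)) stopf("scores and uncertainties misaligned")
  ord <- order(sc)                       # ascending candidate cutoffs
  sc_s <- sc[ord]; bad_s <- (un > unc_threshold)[ord]
  n <- length(sc_s)
  # for candidate sc_s[i], the "above" set excludes ties with the
  # candidate value; cumulative counts give O(n log n) evaluation
  n_le <- findInterval(sc_s, sc_s)       # cells with score <= candidate
  bad_cum <- cumsum(bad_s)
  n_above <- n - n_le
  bad_above <- bad_cum[n] - bad_cum[n_le]
  ok <- n_above > 0L & bad_above / n_above < max_unreliable_frac
  if (any(ok)) sc_s[which(ok)[1]] else NA_real_
}

#' Gaussian-mixture binarization of senescence scores
#'
#' One-dimensional Gaussian mixtures with unequal variances are fitted to
#' all scores for K = `k_min`..`k_max` components and the K with the
#' lowest AIC is kept; cells are assigned to components by maximum
#' posterior. Components whose 5% normal quantile (`mu - 1.6449 sd`)
#' exceeds the cutoff qualify; the qualifying component with the smallest
#' mean is the pivot, and a cell is senescent when its component mean is
#' `>=` the pivot mean. With no qualifying component (or a `NA` cutoff)
#' every cell is non-senescent.
#'
#' @param scores `sen_scores` tibble or numeric vector.
#' @param cutoff score cutoff from [score_cutoff()] (may be `NA`).
#' @param k_min,k_max range of component counts (default 2..10).
#' @param seed RNG seed for the mixture fit.
#' @return list with `senescent` (logical per cell) and `mixture` (list:
#'   `K`, `means`, `sds`, `weights`, `aic` per candidate K, `assignment`,
#'   `pivot`).
#' @importFrom mclust Mclust mclustBIC
#' @export
gmm_binarize <- function(scores, cutoff, k_min = 2L, k_max = 10L, seed = 1L) {
  sc <- if (is.data.frame(scores)) scores$score else as.numeric(scores)
  n <- length(sc)
  if (n < 5L * k_min) stopf("need at least %d cells for a %d-component mixture",
                            5L * k_min, k_min)
  if (is.na(cutoff)) {
    return(list(senescent = rep(FALSE, n), mixture = NULL))
  }
  set.seed(seed)
  ks <- k_min:k_max
  fits <- vector("list", length(ks))
  aic <- rep(NA_real_, length(ks))
  for (i in seq_along(ks)) {
    f <- tryCatch(
      mclust::Mclust(sc, G = ks[i], modelNames = "V", verbose = FALSE),
      error = function(e) NULL)
    if (is.null(f) || is.null(f$loglik) || !is.finite(f$loglik)) {
      warnf("mixture fit failed for K = %d; skipped", ks[i])
      next
    }
    fits[[i]] <- f
    aic[i] <- 2 * f$df - 2 * f$loglik
  }
  if (all(is.na(aic))) stopf("every mixture fit failed")
  best <- which.min(aic)
  f <- fits[[best]]
  means <- as.numeric(f$parameters$mean)
  sds <- sqrt(as.numeric(f$parameters$variance$sigmasq))
  if (length(sds) == 1L) sds <- rep(sds, length(means))
  weights <- as.numeric(f$parameters$pro)
  assignment <- as.integer(f$classification)

  z05 <- -1.6449                         # 5% normal quantile, fixed constant
  qualifying <- which(means + sds * z05 > cutoff)
  if (!length(qualifying)) {
    sen <- rep(FALSE, n); pivot <- NA_integer_
  } else {
    pivot <- qualifying[which.min(means[qualifying])]
    sen_components <- which(means >= means[pivot])
    sen <- assignment %in% sen_components
  }
  list(senescent = sen,
       mixture = list(K = ks[best], means = means, sds = sds,
                      weights = weights, aic = stats::setNames(aic, ks),
                      assignment = assignment, pivot = pivot))
}

#' Binarize continuous senescence scores
#'
#' The full two-step procedure: per-cell permutation-null uncertainties,
#' the uncertainty-based score cutoff, then Gaussian-mixture assignment of
#' senescent cells.
#'
#' @inheritParams permutation_uncertainty
#' @inheritParams score_cutoff
#' @inheritParams gmm_binarize
#' @return the `sen_scores` tibble with added columns `uncertainty` and
#'   `senescent`; attributes `cutoff` and `mixture`.
#' @export
binarize_scores <- function(fit, Xp, scores, n_perm = 50L, seed = 1L,
                            max_unreliable_frac = 0.01, unc_threshold = 0.5,
                            k_min = 2L, k_max = 10L) {
  unc <- permutation_uncertainty(fit, Xp, scores, n_perm = n_perm, seed = seed)
  cutoff <- score_cutoff(scores, unc, max_unreliable_frac, unc_threshold)
  gb <- gmm_binarize(scores, cutoff, k_min = k_min, k_max = k_max, seed = seed)
  scores$uncertainty <- unc$uncertainty
  scores$senescent <- gb$senescent
  attr(scores, "cutoff") <- cutoff
  attr(scores, "mixture") <- gb$mixture
  attr(scores, "n_perm") <- as.integer(n_perm)
  scores
}
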