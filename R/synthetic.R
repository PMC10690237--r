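#' Synthetic-data configuration
#'
#' The generator emulates the data-generating assumptions of the scoring
#' model: counts follow a zero-inflated negative binomial whose log-mean
#' is driven by two independent standard-normal latent factors — a
#' senescence factor `s_j` loading (with induce/inhibit signs) on a block
#' of signature genes, and a nuisance factor `u_j` loading on a disjoint
#' gene block — plus a per-cell library factor.
#'
#' @param n_cells number of cells (default 2000).
#' @param n_genes total genes (default 150).
#' @param n_signature signature genes carrying the senescence factor
#'   (default 39).
#' @param n_nuisance genes carrying the nuisance factor (default 30).
#' @param frac_senescent fraction of cells labeled senescent (default
#'   0.1).
#' @param effect_size log-scale loading of the senescence factor on
#'   signature genes (default 2).
#' @param nuisance_size log-scale loading of the nuisance factor (default
#'   1).
#' @param induce_frac fraction of signature genes with positive (induce)
#'   loading (default 0.75; the rest load negatively, i.e. inhibit).
#' @param baseline_logmean range of per-gene baseline log means (default
#'   log mean counts between ~0.4 and ~4.5).
#' @param dispersion range of per-gene NB dispersions theta.
#' @param dropout range of per-gene dropout probabilities pi.
#' @param libsize_sd sd of the per-cell log-normal library factor.
#' @param mode `"continuous"` (graded senescence: `s_j ~ N(0,1)`, truth =
#'   top `frac_senescent` quantile) or `"discrete"` (two well-separated
#'   modes, for binarization tests).
#' @param seed RNG seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_cells = 2000L, n_genes = 150L, n_signature = 39L,
                       n_nuisance = 30L, frac_senescent = 0.1,
                       effect_size = 2, nuisance_size = 1,
                       induce_frac = 0.75,
                       baseline_logmean = c(-1, 1.5),
                       dispersion = c(1, 10), dropout = c(0.05, 0.3),
                       libsize_sd = 0.3,
                       mode = c("continuous", "discrete"), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(frac_senescent > 0, frac_senescent < 1,
            n_signature + n_nuisance <= n_genes,
            diff(baseline_logmean) >= 0, diff(dispersion) >= 0,
            diff(dropout) >= 0, all(dropout >= 0), all(dropout < 1),
            libsize_sd >= 0, induce_frac >= 0, induce_frac <= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a ZINB count matrix with known senescence truth
#'
#' Draws `mu_ij = L_j * exp(beta0_i + beta1_i s_j + beta2_i u_j)` and
#' `x_ij ~ ZINB(pi_i, mu_ij, theta_i)`. `beta1_i = +/- effect_size` on the
#' signature genes (sign by the induce/inhibit split), `beta2_i = +/-
#' nuisance_size` on a disjoint nuisance block, 0 elsewhere. The first
#' induce-direction signature gene is named `CDKN1A` so the default sign
#' anchor exists in simulated data. Fully seeded and reproducible.
#'
#' @param cfg a [sim_config()].
#' @return list with `counts` (genes x cells integer matrix), `truth`
#'   (tibble: `cell_id`, `s`, `u`, `library_factor`, `is_senescent`),
#'   `gene_truth` (tibble: `gene`, `beta0`, `beta1`, `beta2`, `theta`,
#'   `dropout`), and `signature` (a [gene_set()] with directions).
#' @export
simulate_counts <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_cells; G <- cfg$n_genes
  n_sig <- cfg$n_signature; n_nui <- cfg$n_nuisance

  # latent factors
  if (cfg$mode == "continuous") {
    s <- stats::rnorm(n)
    is_sen <- s > stats::quantile(s, 1 - cfg$frac_senescent)
  } else {
    n_sen <- round(cfg$frac_senescent * n)
    is_sen <- seq_len(n) %in% sample.int(n, n_sen)
    s <- stats::rnorm(n, sd = 0.25) + ifelse(is_sen, 2, 0)
  }
  u <- stats::rnorm(n)
  L <- exp(stats::rnorm(n, sd = cfg$libsize_sd))

  # gene-level parameters
  n_ind <- round(cfg$induce_frac * n_sig)
  sig_sign <- c(rep(1, n_ind), rep(-1, n_sig - n_ind))
  beta1 <- c(sig_sign * cfg$effect_size, rep(0, G - n_sig))
  beta2 <- c(rep(0, n_sig),
             sample(c(-1, 1), n_nui, replace = TRUE) * cfg$nuisance_size,
             rep(0, G - n_sig - n_nui))
  beta0 <- stats::runif(G, cfg$baseline_logmean[1], cfg$baseline_logmean[2])
  theta <- stats::runif(G, cfg$dispersion[1], cfg$dispersion[2])
  drop_p <- stats::runif(G, cfg$dropout[1], cfg$dropout[2])

  gene_ids <- c("CDKN1A",
                if (n_sig > 1) sprintf("SEN%03d", 2:n_sig),
                if (n_nui > 0) sprintf("NUI%03d", seq_len(n_nui)),
                if (G - n_sig - n_nui > 0)
                  sprintf("BG%04d", seq_len(G - n_sig - n_nui)))
  cell_ids <- sprintf("cell%05d", seq_len(n))

  mu <- exp(outer(beta0, rep(1, n)) + outer(beta1, s) + outer(beta2, u))
  mu <- sweep(mu, 2L, L, "*")
  x <- matrix(stats::rnbinom(G * n, mu = mu, size = theta), G, n)
  keep <- matrix(stats::rbinom(G * n, 1L, 1 - drop_p), G, n)
  counts <- x * keep
  dimnames(counts) <- list(gene_ids, cell_ids)

  direction <- stats::setNames(ifelse(sig_sign > 0, "induce", "inhibit"),
                               gene_ids[seq_len(n_sig)])
  list(
    counts = counts,
    truth = tibble::tibble(cell_id = cell_ids, s = s, u = u,
                           library_factor = L, is_senescent = is_sen),
    gene_truth = tibble::tibble(gene = gene_ids, beta0 = beta0,
                                beta1 = beta1, beta2 = beta2, theta = theta,
                                dropout = drop_p),
    true_mu = mu,
    signature = gene_set("synthetic_signature", gene_ids[seq_len(n_sig)],
                         direction = direction)
  )
}
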