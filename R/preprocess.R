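#' Per-cell size factors
#'
#' Library size of each cell divided by the median library size across
#' cells, so the median size factor is 1. These factors rescale the
#' model's library-free mean matrix back to the count scale inside the
#' likelihood.
#'
#' @param counts numeric genes x cells matrix of non-negative counts.
#' @return named numeric vector of positive size factors, one per cell.
#' @export
compute_size_factors <- function(counts) {
  counts <- assert_count_matrix(counts)
  ls <- colSums(counts)
  if (any(ls == 0))
    stopf("cell(s) with zero total count: %s",
          paste(colnames(counts)[ls == 0], collapse = ", "))
  stats::setNames(ls / stats::median(ls), colnames(counts))
}

#' Library-size normalization and log transform
#'
#' Each entry becomes `log(1 + count / s_j)` with `s_j` the cell's size
#' factor, removing library-size differences up to the median rescale.
#'
#' @inheritParams compute_size_factors
#' @param size_factors optional precomputed [compute_size_factors()] output.
#' @return numeric matrix of the same dimensions.
#' @export
normalize_log <- function(counts, size_factors = NULL) {
  counts <- assert_count_matrix(counts)
  s <- size_factors %||% compute_size_factors(counts)
  log1p(sweep(counts, 2L, s, "/"))
}

#' Subset to a signature and standardize per gene
#'
#' Restricts a log-normalized matrix to the genes of a signature and
#' standardizes every retained gene row to zero mean and unit standard
#' deviation across cells (population convention, divide by n).
#' Zero-variance rows are dropped with a warning: targeted panels often
#' contain markers with no detected expression.
#'
#' @param lognorm numeric genes x cells matrix, e.g. from
#'   [normalize_log()].
#' @param geneset a [gene_set()] (or character vector of gene symbols).
#' @param min_genes minimum number of signature genes that must be present
#'   (default 5).
#' @return a `scaled_matrix`: list with `values` (genes x cells, each row
#'   mean 0 / sd 1), `per_gene_mean`, `per_gene_sd`.
#' @export
subset_and_scale <- function(lognorm, geneset, min_genes = 5L) {
  genes <- if (inherits(geneset, "gene_set")) geneset$genes else as.character(geneset)
  present <- intersect(genes, rownames(lognorm))
  if (length(present) < min_genes)
    stopf("only %d of %d signature genes present (need >= %d); missing: %s",
          length(present), length(genes), min_genes,
          paste(utils::head(setdiff(genes, rownames(lognorm)), 10), collapse = ", "))
  m <- lognorm[present, , drop = FALSE]
  mu <- rowMeans(m)
  sd_pop <- sqrt(rowMeans((m - mu)^2))
  drop <- sd_pop == 0
  if (any(drop)) {
    warnf("dropping %d zero-variance signature gene(s): %s", sum(drop),
          paste(present[drop], collapse = ", "))
    m <- m[!drop, , drop = FALSE]; mu <- mu[!drop]; sd_pop <- sd_pop[!drop]
    if (nrow(m) < min_genes)
      stopf("fewer than %d signature genes with non-zero variance", min_genes)
  }
  structure(list(values = (m - mu) / sd_pop,
                 per_gene_mean = mu, per_gene_sd = sd_pop),
            class = "scaled_matrix")
}

#' @export
print.scaled_matrix <- function(x, ...) {
  cat(sprintf("<scaled_matrix> %d genes x %d cells (per-gene mean 0, sd 1)\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' ZINB-autoencoder denoising of a count matrix
#'
#' Fits a wider ZINB autoencoder (default 64-32-64, ReLU bottleneck, no
#' correlation penalty) on all genes and replaces each count with the
#' fitted ZINB mean rescaled by the cell's size factor. Genes whose
#' log-normalized expression is constant across cells (typically all-zero)
#' are passed through unchanged. The output is real-valued; downstream
#' likelihoods generalize the factorial through the gamma function.
#'
#' @param counts genes x cells count matrix.
#' @param enabled set `FALSE` to return the input unchanged.
#' @param hidden,bottleneck encoder/decoder and bottleneck widths.
#' @param config a [train_config()]; its `lambda` is ignored (forced to 0).
#' @return genes x cells matrix of non-negative denoised values.
#' @export
denoise <- function(counts, enabled = TRUE, hidden = 64L, bottleneck = 32L,
                    config = train_config()) {
  counts <- assert_count_matrix(counts)
  if (!enabled) return(counts)
  s <- compute_size_factors(counts)
  ln <- normalize_log(counts, s)
  mu <- rowMeans(ln)
  sd_pop <- sqrt(rowMeans((ln - mu)^2))
  model_rows <- sd_pop > 0
  if (sum(model_rows) < 2L) stopf("too few variable genes to denoise")
  A  <- t((ln[model_rows, , drop = FALSE] - mu[model_rows]) / sd_pop[model_rows])
  Xc <- t(counts[model_rows, , drop = FALSE])
  config$lambda <- 0
  fit <- tryCatch(
    fit_network(A, Xc, s, config, enc = hidden, bottleneck = bottleneck,
                dec = hidden, bottleneck_activation = "relu"),
    error = function(e) {
      if (grepl("non-finite", conditionMessage(e)))
        stopf("denoising diverged (%s); rerun with denoise disabled",
              conditionMessage(e))
      stop(e)
    })
  fw <- nn_forward(A, fit$params, "relu")
  out <- counts
  out[model_rows, ] <- t(fw$Mp * s)
  out
}

#' Prepare model inputs from a raw count matrix
#'
#' Runs the fixed preprocessing chain — optional denoising, library-size
#' log-normalization, signature subsetting, per-gene standardization — and
#' returns everything the model consumes.
#'
#' @param counts genes x cells count matrix.
#' @param geneset scoring signature (default [default_signature()]).
#' @param denoise logical; fit the denoising autoencoder first.
#' @param min_genes minimum signature overlap, see [subset_and_scale()].
#' @param denoise_config [train_config()] for the denoising stage.
#' @return list with `X` (denoised counts restricted to the retained
#'   signature genes), `Xp` (the [subset_and_scale()] result), and `s`
#'   (size factors).
#' @export
prepare_inputs <- function(counts, geneset = default_signature(),
                           denoise = TRUE, min_genes = 5L,
                           denoise_config = train_config()) {
  counts <- assert_count_matrix(counts)
  dn <- senoscore::denoise(counts, enabled = denoise, config = denoise_config)
  s <- compute_size_factors(dn)
  ln <- normalize_log(dn, s)
  Xp <- subset_and_scale(ln, geneset, min_genes = min_genes)
  list(X = dn[rownames(Xp$values), , drop = FALSE], Xp = Xp, s = s)
}
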