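#' Training configuration
#'
#' Defaults follow the published schedule: full-batch Adam at learning
#' rate 0.005 for up to 300 epochs, a fixed seeded 10% validation split
#' whose ZINB loss (penalty excluded) drives the schedule — the learning
#' rate is halved after 10 epochs without improvement and training stops
#' after 30.
#'
#' @param epochs maximum number of epochs.
#' @param lr initial Adam learning rate.
#' @param lambda bottleneck correlation penalty weight.
#' @param val_fraction fraction of cells held out for validation.
#' @param lr_patience epochs without validation improvement before the
#'   learning rate is halved.
#' @param stop_patience epochs without improvement before training stops.
#' @param seed seed driving initialization and the validation split.
#' @param restore_best if `TRUE`, return the weights from the best
#'   validation epoch instead of the final epoch.
#' @param improve_tol relative tolerance defining "improvement".
#' @param verbose print a line per epoch to stderr.
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 300L, lr = 0.005, lambda = 1,
                         val_fraction = 0.1, lr_patience = 10L,
                         stop_patience = 30L, seed = 1L,
                         restore_best = FALSE, improve_tol = 1e-6,
                         verbose = FALSE) {
  stopifnot(val_fraction > 0, val_fraction < 1, lr_patience < stop_patience,
            epochs >= 1, lr > 0, lambda >= 0)
  structure(list(epochs = as.integer(epochs), lr = lr, lambda = lambda,
                 val_fraction = val_fraction,
                 lr_patience = as.integer(lr_patience),
                 stop_patience = as.integer(stop_patience),
                 seed = as.integer(seed), restore_best = restore_best,
                 improve_tol = improve_tol, verbose = verbose),
            class = "train_config")
}

# Core training loop shared by the scoring model and the denoiser.
# A: cells x genes scaled input; Xc: cells x genes counts; s: size factors.
fit_network <- function(A, Xc, s, config, enc = 32L, bottleneck = 2L,
                        dec = 32L, bottleneck_activation = "tanh") {
  n <- nrow(A)
  if (n < 20L) stopf("need at least 20 cells to train (got %d)", n)
  set.seed(config$seed)
  params <- new_params(ncol(A), enc = enc, bottleneck = bottleneck, dec = dec)
  n_val <- max(2L, round(config$val_fraction * n))
  if (n - n_val < 2L) stopf("too few training cells after the validation split")
  idx_val <- sort(sample.int(n, n_val))
  idx_tr <- setdiff(seq_len(n), idx_val)

  Atr <- A[idx_tr, , drop = FALSE]; Xtr <- Xc[idx_tr, , drop = FALSE]
  Avl <- A[idx_val, , drop = FALSE]; Xvl <- Xc[idx_val, , drop = FALSE]
  str <- s[idx_tr]; svl <- s[idx_val]

  state <- adam_init(params)
  lr <- config$lr
  best <- Inf; best_params <- NULL; bad <- 0L
  stop_epoch <- config$epochs; stop_reason <- "max_epochs"
  hist <- vector("list", config$epochs)
  warned <- FALSE

  for (ep in seq_len(config$epochs)) {
    lg <- withCallingHandlers(
      nn_loss_grad(Atr, Xtr, str, params, lambda = config$lambda,
                   bottleneck_activation = bottleneck_activation,
                   warn_degenerate = !warned),
      warning = function(w) { warned <<- TRUE; invokeRestart("muffleWarning") })
    if (!is.finite(lg$total))
      stopf("non-finite training loss at epoch %d", ep)
    upd <- adam_step(params, lg$grads, state, lr)
    params <- upd$params; state <- upd$state

    val_nll <- nn_nll(Xvl, svl, nn_forward(Avl, params, bottleneck_activation))
    if (!is.finite(val_nll))
      stopf("non-finite validation loss at epoch %d", ep)
    hist[[ep]] <- c(epoch = ep, train_total = lg$total, train_nll = lg$nll,
                    train_penalty = lg$penalty, val_nll = val_nll, lr = lr)
    if (config$verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f  lr %.5f",
                      ep, lg$total, val_nll, lr))

    improved <- (best - val_nll) > config$improve_tol * abs(best) ||
      (is.infinite(best) && is.finite(val_nll))
    if (improved) {
      best <- val_nll; bad <- 0L
      if (config$restore_best) best_params <- params
    } else {
      bad <- bad + 1L
      if (bad >= config$stop_patience) {
        stop_epoch <- ep; stop_reason <- "early_stop"; break
      }
      if (bad %% config$lr_patience == 0L) lr <- lr / 2
    }
  }
  if (config$restore_best && !is.null(best_params)) params <- best_params
  history <- tibble::as_tibble(do.call(rbind, hist[!vapply(hist, is.null, logical(1))]))
  list(params = params, history = history, stop_epoch = stop_epoch,
       stop_reason = stop_reason, best_val_nll = best,
       idx_val = idx_val)
}

#' Fit the senescence-scoring autoencoder
#'
#' Trains the G-32-2-32 ZINB autoencoder on the preprocessed inputs.
#' Weights are Glorot-uniform initialized from the config seed; a fixed
#' seeded `val_fraction` of cells is held out and its ZINB negative
#' log-likelihood (penalty excluded) is monitored every epoch for the
#' learning-rate/stopping schedule. The final-epoch weights are returned
#' unless `restore_best = TRUE`.
#'
#' @param X genes x cells (denoised) count matrix on the signature genes,
#'   e.g. `prepare_inputs()$X`.
#' @param Xp matching `scaled_matrix`, e.g. `prepare_inputs()$Xp`.
#' @param s size factors, e.g. `prepare_inputs()$s`.
#' @param config a [train_config()].
#' @return a `sen_fit` object: `params`, `history` (per-epoch tibble with
#'   train/validation losses and learning rate), `stop_epoch`,
#'   `stop_reason`, `genes`, `scaling`, `config`, `validation_cells`.
#' @export
sen_train <- function(X, Xp, s, config = train_config()) {
  stopifnot(inherits(Xp, "scaled_matrix"), inherits(config, "train_config"))
  if (!identical(rownames(X), rownames(Xp$values)))
    stopf("`X` and `Xp` must carry the same genes in the same order")
  if (ncol(X) != ncol(Xp$values) || ncol(X) != length(s))
    stopf("cell dimensions of X, Xp and s disagree")
  res <- fit_network(t(Xp$values), t(X), s, config)
  structure(list(params = res$params, history = res$history,
                 stop_epoch = res$stop_epoch, stop_reason = res$stop_reason,
                 best_val_nll = res$best_val_nll,
                 genes = rownames(Xp$values),
                 scaling = list(mean = Xp$per_gene_mean, sd = Xp$per_gene_sd),
                 validation_cells = colnames(X)[res$idx_val],
                 config = config),
            class = "sen_fit")
}

#' @export
print.sen_fit <- function(x, ...) {
  cat(sprintf(paste0("<sen_fit> ZINB autoencoder, %d genes, %d parameters\n",
                     "  stopped at epoch %d (%s), best validation NLL %.4f\n"),
              length(x$genes), n_learnable(x$params), x$stop_epoch,
              x$stop_reason, x$best_val_nll))
  invisible(x)
}
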