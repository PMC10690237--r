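#' The ZINB autoencoder
#'
#' The scoring model encodes the standardized signature matrix X' through a
#' 32-neuron ReLU encoder into a two-neuron tanh bottleneck, decodes through
#' 32 ReLU neurons, and emits three output heads per gene — sigmoid dropout
#' probabilities, exp means and exp dispersions of a zero-inflated negative
#' binomial. The objective is the mean ZINB negative log-likelihood of the
#' (denoised) counts plus `lambda` times the squared Pearson correlation of
#' the two pre-activation bottleneck neurons, which pushes the two latent
#' axes to carry independent information so one of them can specialize in
#' senescence.
#'
#' @name model
NULL

#' Closed-form learnable parameter count
#'
#' For `G` input genes the six dense layers (each with a bias vector)
#' contribute `(32G + 32) + (64 + 2) + (64 + 32) + 3 (32G + G)` scalars,
#' i.e. `131 G + 194`. For the default 39-gene signature this is 5303.
#'
#' @param G number of input genes, `>= 1`.
#' @return integer parameter count.
#' @examples
#' count_parameters(39)  # 5303
#' @export
count_parameters <- function(G) {
  if (!is.numeric(G) || length(G) != 1 || G < 1 || G != round(G))
    stopf("`G` must be a positive integer")
  as.integer(131 * G + 194)
}

#' Instantiate model parameters
#'
#' Glorot-uniform weight matrices and zero biases for the fixed
#' G-32-2-32 architecture, seeded.
#'
#' @param G number of input genes.
#' @param seed RNG seed for the initialization.
#' @return a `sen_params` list of six weight matrices and six bias vectors.
#' @export
init_params <- function(G, seed = 1L) {
  if (G < 1) stopf("`G` must be a positive integer")
  set.seed(seed)
  new_params(as.integer(G))
}

#' Count learnable scalars by introspection
#'
#' Sums the lengths of every weight matrix and bias vector of an
#' instantiated parameter set; agrees with [count_parameters()].
#'
#' @param params a `sen_params` object (or a fitted model's `$params`).
#' @return integer.
#' @export
n_learnable <- function(params) {
  if (inherits(params, "sen_fit")) params <- params$params
  as.integer(n_learnable_params(params))
}

#' Forward pass of the model
#'
#' @param params a `sen_params` object.
#' @param Xp a `scaled_matrix` from [subset_and_scale()] (or a plain
#'   genes x cells matrix).
#' @return list with per-cell layer values: `E` (encoder), `H`
#'   (pre-activation bottleneck, columns h1/h2), `B = tanh(H)`, `D`
#'   (decoder), and per-gene-per-cell `Pi` (dropout, in (0,1)), `Mp`
#'   (library-free means, > 0), `Th` (dispersions, > 0); all matrices have
#'   cells as rows.
#' @export
model_forward <- function(params, Xp) {
  if (inherits(params, "sen_fit")) params <- params$params
  v <- if (inherits(Xp, "scaled_matrix")) Xp$values else Xp
  sizes <- attr(params, "sizes")
  if (nrow(v) != sizes[["G"]])
    stopf("input has %d genes but the model expects %d", nrow(v), sizes[["G"]])
  fw <- nn_forward(t(v), params, "tanh")
  fw[c("E", "H", "B", "D", "Pi", "Mp", "Th")]
}

#' Evaluate the training objective
#'
#' Mean ZINB negative log-likelihood of the counts under the forward
#' outputs (library-free means multiplied by the size factors) plus
#' `lambda` times the squared Pearson correlation of h1 and h2.
#'
#' @param X genes x cells (denoised) count matrix on the model's genes.
#' @param s size factors, one per cell.
#' @param forward output of [model_forward()].
#' @param lambda correlation penalty weight, `>= 0` (default 1).
#' @return list with `total`, `nll`, `penalty`, `lambda`, `rho`.
#' @export
model_loss <- function(X, s, forward, lambda = 1) {
  if (lambda < 0) stopf("`lambda` must be >= 0")
  Xc <- t(X)
  mu <- clip(forward$Mp * s, 1e-8, 1e8)
  nll <- -mean(zinb_logpmf(Xc, forward$Pi, mu, forward$Th))
  rho <- bottleneck_rho(forward$H)
  penalty <- 0
  if (is.na(rho)) {
    warnf("a bottleneck neuron is constant across cells; penalty set to 0")
    rho <- 0
  } else penalty <- lambda * rho^2
  list(total = nll + penalty, nll = nll, penalty = penalty,
       lambda = lambda, rho = rho)
}

#' Save / load a fitted model
#'
#' Serializes the full fitted state (weights, gene order, scaling
#' statistics, size-factor convention, package version) to a single file
#' that reloads bit-exactly.
#'
#' @param fit a `sen_fit` object from [sen_train()].
#' @param path file path.
#' @return `path`, invisibly (`write_model`); the `sen_fit`
#'   (`read_model`).
#' @export
write_model <- function(fit, path) {
  stopifnot(inherits(fit, "sen_fit"))
  fit$version <- as.character(utils::packageVersion("senoscore"))
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  fit <- readRDS(path)
  if (!inherits(fit, "sen_fit")) stopf("file does not contain a fitted model")
  fit
}
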