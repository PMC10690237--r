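# Fixtures built in code, shared across test files.

# small labelled count matrix with ids
toy_counts <- function(G = 6, n = 8, seed = 1, lambda = 4) {
  set.seed(seed)
  m <- matrix(rpois(G * n, lambda), G, n)
  dimnames(m) <- list(paste0("g", seq_len(G)), paste0("c", seq_len(n)))
  m
}

# nine-member toy gene-set collection with controlled membership counts
toy_collection <- function() {
  sets <- lapply(1:9, function(i) {
    genes <- c("CORE1", "CORE2",                     # in all nine
               if (i <= 5) "FIVE1",                  # in exactly five
               if (i <= 4) "FOUR1",                  # in exactly four
               paste0("UNIQ", i))                    # private to set i
    dir <- if (i %% 2 == 0) c(CORE1 = "induce") else c(CORE1 = "inhibit")
    if (i <= 8) dir <- c(dir, CORE2 = "induce")
    gene_set(paste0("set", i), genes, direction = dir)
  })
  gene_set_collection(sets)
}

# a small simulated dataset + preprocessed inputs + fitted model, computed
# once per test run (training is seconds at this size)
.fitted_cache <- new.env(parent = emptyenv())
fitted_small <- function() {
  if (!is.null(.fitted_cache$res)) return(.fitted_cache$res)
  sim <- simulate_counts(sim_config(n_cells = 300, n_genes = 60,
                                    n_signature = 15, n_nuisance = 10,
                                    seed = 101))
  inp <- prepare_inputs(sim$counts, sim$signature, denoise = FALSE)
  fit <- sen_train(inp$X, inp$Xp, inp$s,
                   train_config(epochs = 120, seed = 101))
  scores <- score_cells(fit, inp$Xp)
  .fitted_cache$res <- list(sim = sim, inp = inp, fit = fit, scores = scores)
  .fitted_cache$res
}

# a fit whose first bottleneck neuron is the mean signature z-score and
# whose second neuron is constant (used by neuron-selection tests)
constructed_fit <- function(G, swap = FALSE) {
  params <- init_params(G, seed = 1)
  for (nm in names(params)) params[[nm]][] <- 0
  # unit weights keep integer inputs exact under reordering
  params$W_e[, 1] <- 1
  params$b_e[] <- 10
  k <- if (swap) 2L else 1L
  params$W_b[1, k] <- 1
  params$b_b[k] <- -10
  structure(list(params = params, genes = paste0("g", seq_len(G)),
                 history = tibble::tibble(), stop_epoch = 0L,
                 stop_reason = "constructed", best_val_nll = NA_real_,
                 scaling = NULL, validation_cells = character(0),
                 config = train_config()),
            class = "sen_fit")
}

# independent direct-formula ZINB density (non-log path where feasible)
zinb_pmf_oracle <- function(x, pi, mu, theta) {
  nb <- exp(lgamma(x + theta) - lgamma(theta) - lgamma(x + 1)) *
    (theta / (theta + mu))^theta * (mu / (mu + theta))^x
  pi * (x == 0) + (1 - pi) * nb
}
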