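test_that("closed-form parameter count matches introspection of instantiated models", {
  expect_equal(count_parameters(39), 5303L)
  expect_equal(count_parameters(1), 325L)
  expect_equal(count_parameters(10), 1504L)
  for (G in c(1:5, 20, 39, 60))
    expect_identical(n_learnable(init_params(G)), count_parameters(G))
  expect_error(count_parameters(0), "positive")
})

test_that("forward pass reproduces the activation chain", {
  G <- 3; n <- 5
  p <- init_params(G, seed = 2)
  for (nm in names(p)) p[[nm]][] <- 0
  Xp <- matrix(rnorm(G * n), G, n,
               dimnames = list(paste0("g", 1:G), paste0("c", 1:n)))
  fw <- model_forward(p, Xp)
  expect_true(all(fw$Pi == 0.5))
  expect_true(all(fw$Mp == 1))
  expect_true(all(fw$Th == 1))
  expect_true(all(fw$B == 0))

  # hand-traced chain on random weights (independent of the package code)
  p2 <- init_params(G, seed = 7)
  fw2 <- model_forward(p2, Xp)
  A <- t(Xp)
  E <- pmax(sweep(A %*% p2$W_e, 2, p2$b_e, "+"), 0)
  H <- sweep(E %*% p2$W_b, 2, p2$b_b, "+")
  D <- pmax(sweep(tanh(H) %*% p2$W_d, 2, p2$b_d, "+"), 0)
  expect_equal(fw2$H, H, tolerance = 1e-12)
  expect_equal(fw2$Pi, 1 / (1 + exp(-sweep(D %*% p2$W_pi, 2, p2$b_pi, "+"))),
               tolerance = 1e-12)
  expect_equal(fw2$Mp, exp(sweep(D %*% p2$W_m, 2, p2$b_m, "+")),
               tolerance = 1e-12)
  # negative encoder pre-activations are zeroed
  p3 <- p; p3$b_e[] <- -1
  expect_true(all(model_forward(p3, Xp)$E == 0))
  # per-cell computation: a duplicated cell duplicates its outputs
  Xpd <- cbind(Xp, dup = Xp[, 1])
  fwd <- model_forward(p2, Xpd)
  expect_equal(fwd$B[n + 1, ], fwd$B[1, ])
})

test_that("ZINB log-density matches direct evaluation and normalizes", {
  expect_equal(zinb_logpmf(0, 0.5, 1, 1), log(0.75), tolerance = 1e-12)
  expect_equal(zinb_logpmf(1, 0.5, 1, 1), log(0.5 * 0.25), tolerance = 1e-12)
  grid <- expand.grid(x = c(0, 1, 2, 5, 17), pi = c(0.01, 0.3, 0.9),
                      mu = c(0.1, 1, 8), theta = c(0.5, 2, 50))
  got <- with(grid, zinb_logpmf(x, pi, mu, theta))
  want <- log(with(grid, zinb_pmf_oracle(x, pi, mu, theta)))
  # keep to where the linear-scale reference itself is representable
  keep <- want > -600
  expect_gt(sum(keep), 100)
  expect_equal(got[keep], want[keep], tolerance = 1e-10)
  expect_true(all(got <= 0))
  # pi -> 0 recovers the plain NB density
  expect_equal(zinb_logpmf(3, 1e-12, 2, 5),
               dnbinom(3, mu = 2, size = 5, log = TRUE), tolerance = 1e-9)
  # the pmf sums to one over the support
  for (par in list(c(0.3, 2, 1), c(0.05, 10, 5), c(0.8, 0.5, 0.7))) {
    tot <- sum(exp(zinb_logpmf(0:3000, par[1], par[2], par[3])))
    expect_equal(tot, 1, tolerance = 1e-6)
  }
  expect_error(zinb_logpmf(1, 1.5, 1, 1), "pi")
  expect_error(zinb_logpmf(1, 0.5, -1, 1), "mu")
})

test_that("the objective is the mean ZINB NLL plus the correlation penalty", {
  G <- 2; n <- 3
  set.seed(4)
  p <- init_params(G, seed = 4)
  Xp <- matrix(rnorm(G * n), G, n,
               dimnames = list(c("g1", "g2"), c("a", "b", "c")))
  X <- matrix(rpois(G * n, 4), G, n, dimnames = dimnames(Xp))
  s <- c(a = 0.8, b = 1, c = 1.4)
  fw <- model_forward(p, Xp)
  lv <- model_loss(X, s, fw, lambda = 1.7)
  # independently coded sum over entries + hand Pearson correlation
  acc <- 0
  for (i in 1:G) for (j in 1:n)
    acc <- acc + log(zinb_pmf_oracle(X[i, j], fw$Pi[j, i],
                                     fw$Mp[j, i] * s[j], fw$Th[j, i]))
  rho <- cor(fw$H[, 1], fw$H[, 2])
  expect_equal(lv$nll, unname(-acc / (G * n)), tolerance = 1e-10)
  expect_equal(lv$penalty, 1.7 * rho^2, tolerance = 1e-10)
  expect_equal(lv$total, lv$nll + lv$penalty, tolerance = 1e-12)
  # penalty off
  expect_equal(model_loss(X, s, fw, lambda = 0)$total,
               model_loss(X, s, fw, lambda = 0)$nll)
  # duplicated bottleneck weights give rho = 1, penalty = lambda
  p2 <- p; p2$W_b[, 2] <- p2$W_b[, 1]; p2$b_b[2] <- p2$b_b[1]
  lv2 <- model_loss(X, s, model_forward(p2, Xp), lambda = 2.5)
  expect_equal(lv2$penalty, 2.5, tolerance = 1e-9)
  # invariant to cell order
  perm <- c(3, 1, 2)
  lvp <- model_loss(X[, perm], s[perm], model_forward(p, Xp[, perm]),
                    lambda = 1.7)
  expect_equal(lvp$total, lv$total, tolerance = 1e-12)
})

test_that("generating ZINB parameters score a lower NLL than perturbed ones", {
  sim <- simulate_counts(sim_config(n_cells = 200, n_genes = 40,
                                    n_signature = 10, n_nuisance = 8,
                                    seed = 12))
  x <- as.vector(sim$counts)
  mu <- as.vector(sim$true_mu)
  theta <- rep(sim$gene_truth$theta, ncol(sim$counts))
  pi_ <- rep(pmin(pmax(sim$gene_truth$dropout, 1e-6), 1 - 1e-6),
             ncol(sim$counts))
  nll_true <- -mean(zinb_logpmf(x, pi_, mu, theta))
  set.seed(13)
  nll_rand <- -mean(zinb_logpmf(x, rep(0.5, length(x)),
                                rep(mean(mu), length(x)),
                                rep(1, length(x))))
  expect_lt(nll_true, nll_rand)
})

test_that("analytic gradients agree with central finite differences", {
  ns <- asNamespace("senoscore")
  set.seed(42)
  n <- 6; G <- 4
  p <- ns$new_params(G, enc = 5, bottleneck = 2, dec = 5)
  # jitter the biases so no ReLU pre-activation sits exactly on its kink
  # (zero-initialized biases leave dead cells at the non-differentiable point)
  for (nm in c("b_e", "b_b", "b_d", "b_pi", "b_m", "b_th"))
    p[[nm]] <- rnorm(length(p[[nm]]), sd = 0.2)
  A <- matrix(rnorm(n * G), n, G)
  Xc <- matrix(rpois(n * G, 3), n, G)
  s <- runif(n, 0.5, 1.5)
  lg <- ns$nn_loss_grad(A, Xc, s, p, lambda = 1.3)
  f <- function(pp) ns$nn_loss_grad(A, Xc, s, pp, lambda = 1.3)$total
  eps <- 1e-5
  for (nm in names(lg$grads)) {
    g <- lg$grads[[nm]]
    for (i in sample(length(g), min(4, length(g)))) {
      pp <- pm <- p
      pp[[nm]][i] <- pp[[nm]][i] + eps
      pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (f(pp) - f(pm)) / (2 * eps)
      expect_equal(g[i], num, tolerance = 1e-4)
    }
  }
})

test_that("a fitted model serializes and reloads bit-exactly", {
  fs <- fitted_small()
  path <- withr::local_tempfile(fileext = ".rds")
  write_model(fs$fit, path)
  back <- read_model(path)
  expect_identical(back$params, fs$fit$params)
  expect_identical(back$genes, fs$fit$genes)
  expect_equal(score_cells(back, fs$inp$Xp)$score, fs$scores$score)
})
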