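test_that("a permutation-invariant encoder yields zero uncertainty everywhere", {
  G <- 6; n <- 25
  set.seed(5)
  # integer-valued input so per-cell sums are exact under any ordering
  v <- matrix(sample(0:5, G * n, replace = TRUE), G, n,
              dimnames = list(paste0("g", 1:G), paste0("c", 1:n)))
  fit <- constructed_fit(G)              # encoder sees only per-cell sums
  sc <- tibble::tibble(cell_id = colnames(v),
                       score = unname(model_forward(fit, v)$B[, 1]))
  attr(sc, "neuron_index") <- 1L
  attr(sc, "flipped") <- FALSE
  unc <- permutation_uncertainty(fit, v, sc, n_perm = 20, seed = 1)
  expect_equal(unc$uncertainty, rep(0, n))
})

test_that("uncertainties live on the 1/n_perm grid and match a brute-force recount", {
  fs <- fitted_small()
  unc <- permutation_uncertainty(fs$fit, fs$inp$Xp, fs$scores,
                                 n_perm = 50, seed = 42)
  expect_true(all(abs(unc$uncertainty * 50 - round(unc$uncertainty * 50)) < 1e-9))

  # independent recount: replay the seeded shuffles and count exceedances
  v <- fs$inp$Xp$values
  k <- attr(fs$scores, "neuron_index")
  sgn <- if (isTRUE(attr(fs$scores, "flipped"))) -1 else 1
  set.seed(42)
  exceed <- numeric(ncol(v))
  for (r in 1:50) {
    vp <- apply(v, 2, sample)
    b <- model_forward(fs$fit, vp)$B[, k]
    exceed <- exceed + unname(sgn * b > fs$scores$score)
  }
  expect_equal(unc$uncertainty, exceed / 50)
})

test_that("the score cutoff is the smallest qualifying observed score", {
  # zero uncertainty everywhere: the minimum score qualifies immediately
  set.seed(3)
  sc <- rnorm(50)
  expect_equal(score_cutoff(sc, rep(0, 50)), min(sc))
  # unreliable below 90, clean above
  sc2 <- 1:100
  un2 <- ifelse(sc2 <= 90, 1, 0)
  expect_equal(score_cutoff(sc2, un2), 90)
  # nothing qualifies
  expect_true(is.na(score_cutoff(sc2, rep(1, 100))))

  # brute-force re-derivation on random data, including tied scores
  for (seed in 1:5) {
    set.seed(seed)
    s <- sample(round(rnorm(80), 1))     # ties on purpose
    u <- runif(80)
    frac <- 0.1
    brute <- NA_real_
    for (c_ in sort(s)) {
      above <- s > c_
      if (sum(above) > 0 && mean(u[above] > 0.5) < frac) { brute <- c_; break }
    }
    expect_identical(score_cutoff(s, u, max_unreliable_frac = frac), brute)
  }
})

test_that("tightening the unreliable fraction never lowers the cutoff", {
  set.seed(11)
  s <- rnorm(200); u <- runif(200)
  cuts <- vapply(c(0.2, 0.1, 0.05, 0.02), function(fr)
    score_cutoff(s, u, max_unreliable_frac = fr), numeric(1))
  cuts <- cuts[!is.na(cuts)]
  expect_true(all(diff(cuts) >= 0))
})

test_that("the mixture step recovers a well-separated senescent mode", {
  set.seed(1)
  x <- c(rnorm(900, 0, 0.2), rnorm(100, 3, 0.2))
  truth <- rep(c(FALSE, TRUE), c(900, 100))
  gb <- gmm_binarize(x, cutoff = 1.5, seed = 1)
  expect_equal(gb$mixture$K, 2L)         # AIC picks the bimodal fit
  expect_gte(mean(gb$senescent == truth), 0.95)
  # pivot re-derivation: smallest-mean component whose 5% quantile clears the cutoff
  m <- gb$mixture
  qual <- which(m$means - 1.6449 * m$sds > 1.5)
  expect_equal(m$pivot, qual[which.min(m$means[qual])])
  # senescent set is upward-closed in component means
  sen_comp <- unique(m$assignment[gb$senescent])
  non_comp <- unique(m$assignment[!gb$senescent])
  if (length(sen_comp) && length(non_comp))
    expect_gt(min(m$means[sen_comp]), max(m$means[non_comp]))

  # a cutoff beyond every component's reach calls nobody
  gb2 <- gmm_binarize(x, cutoff = 10, seed = 1)
  expect_false(any(gb2$senescent))
  # sentinel cutoff skips the fit entirely
  gb3 <- gmm_binarize(x, cutoff = NA_real_)
  expect_false(any(gb3$senescent))
  expect_null(gb3$mixture)
})

test_that("binarize_scores assembles uncertainty, cutoff and labels coherently", {
  fs <- fitted_small()
  sc <- binarize_scores(fs$fit, fs$inp$Xp, fs$scores, n_perm = 30, seed = 7)
  expect_true(all(c("uncertainty", "senescent") %in% names(sc)))
  expect_true(is.logical(sc$senescent))
  cutoff <- attr(sc, "cutoff")
  if (!is.na(cutoff)) {
    # labelled senescent cells come from components above the pivot, hence
    # their mean score exceeds the non-senescent mean
    if (any(sc$senescent) && any(!sc$senescent))
      expect_gt(mean(sc$score[sc$senescent]), mean(sc$score[!sc$senescent]))
  }
})
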