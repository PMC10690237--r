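# Internal autoencoder engine.
#
# All heavy lifting for the ZINB autoencoder lives here: parameter
# initialization, the forward pass, analytic gradients of the objective
# (mean ZINB negative log-likelihood plus the squared-Pearson bottleneck
# penalty), and the Adam update. The scoring model is the fixed
# G -> 32 -> 2(tanh) -> 32 -> {pi, mu, theta} architecture; the optional
# denoising stage reuses the same engine with a wider ReLU bottleneck.
#
# Convention inside this file: cells are ROWS (n x G matrices), the
# transpose of the package's user-facing genes x cells layout.

glorot <- function(fan_in, fan_out) {
  l <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -l, l), fan_in, fan_out)
}

# Parameter container: six dense layers, every layer carries a bias vector.
new_params <- function(G, enc = 32L, bottleneck = 2L, dec = 32L) {
  p <- list(
    W_e  = glorot(G, enc),        b_e  = numeric(enc),
    W_b  = glorot(enc, bottleneck), b_b = numeric(bottleneck),
    W_d  = glorot(bottleneck, dec), b_d = numeric(dec),
    W_pi = glorot(dec, G),        b_pi = numeric(G),
    W_m  = glorot(dec, G),        b_m  = numeric(G),
    W_th = glorot(dec, G),        b_th = numeric(G)
  )
  attr(p, "sizes") <- c(G = G, enc = enc, bottleneck = bottleneck, dec = dec)
  class(p) <- "sen_params"
  p
}

n_learnable_params <- function(p) sum(vapply(p, length, integer(1)))

addb <- function(M, b) sweep(M, 2L, b, "+")

# forward pass; A is cells x genes (already scaled). Returns all
# intermediates needed for the backward pass.
nn_forward <- function(A, p, bottleneck_activation = c("tanh", "relu")) {
  bottleneck_activation <- match.arg(bottleneck_activation)
  Z1 <- addb(A %*% p$W_e, p$b_e)
  E  <- relu(Z1)
  H  <- addb(E %*% p$W_b, p$b_b)
  B  <- if (bottleneck_activation == "tanh") tanh(H) else relu(H)
  Z2 <- addb(B %*% p$W_d, p$b_d)
  D  <- relu(Z2)
  Zpi <- clip(addb(D %*% p$W_pi, p$b_pi), stats::qlogis(.PI_EPS), stats::qlogis(1 - .PI_EPS))
  Zm  <- clip(addb(D %*% p$W_m,  p$b_m), -.Z_CLIP, .Z_CLIP)
  Zth <- clip(addb(D %*% p$W_th, p$b_th), -.Z_CLIP, .Z_CLIP)
  out <- list(Z1 = Z1, E = E, H = H, B = B, Z2 = Z2, D = D,
              Pi = sigmoid(Zpi), Mp = exp(Zm), Th = exp(Zth),
              activation = bottleneck_activation)
  for (nm in c("E", "H", "B", "D", "Pi", "Mp", "Th"))
    if (any(!is.finite(out[[nm]])))
      stopf("non-finite activations in layer %s", nm)
  out
}

# ZINB negative log-likelihood averaged over all entries; Xc cells x genes,
# s length-n size factors (mu = Mp * s per cell).
nn_nll <- function(Xc, s, fw) {
  mu <- clip(fw$Mp * s, 1e-8, 1e8)
  -mean(zinb_logpmf(Xc, fw$Pi, mu, fw$Th))
}

# Pearson correlation of the two pre-activation bottleneck neurons.
bottleneck_rho <- function(H) {
  if (ncol(H) != 2L) return(0)
  if (stats::sd(H[, 1]) == 0 || stats::sd(H[, 2]) == 0) return(NA_real_)
  stats::cor(H[, 1], H[, 2])
}

# Loss + analytic gradients. Returns total/nll/penalty/rho and a gradient
# list with the same names/shapes as the parameter list.
nn_loss_grad <- function(A, Xc, s, p, lambda = 1,
                         bottleneck_activation = "tanh",
                         warn_degenerate = TRUE) {
  fw <- nn_forward(A, p, bottleneck_activation)
  n <- nrow(A); G <- ncol(A)
  Pi <- fw$Pi; Th <- fw$Th
  mu <- clip(fw$Mp * s, 1e-8, 1e8)

  nll <- -mean(zinb_logpmf(Xc, Pi, mu, Th))

  # per-entry d(logpmf)/d(linear predictor) for the three heads
  zero <- Xc == 0
  lc   <- Th * (log(Th) - log(Th + mu))          # log NB(0)
  cc   <- exp(lc)
  dl_zpi <- dl_zm <- dl_zth <- matrix(0, n, G)

  if (any(zero)) {
    p0 <- Pi[zero] + (1 - Pi[zero]) * cc[zero]
    thz <- Th[zero]; muz <- mu[zero]; piz <- Pi[zero]; cz <- cc[zero]
    dl_zpi[zero] <- piz * (1 - piz) * (1 - cz) / p0
    dl_zm[zero]  <- -(1 - piz) * cz * thz * muz / (thz + muz) / p0
    dl_zth[zero] <- (1 - piz) * cz * thz *
      (log(thz) + 1 - log(thz + muz) - thz / (thz + muz)) / p0
  }
  if (any(!zero)) {
    xp <- Xc[!zero]; thp <- Th[!zero]; mup <- mu[!zero]
    dl_zpi[!zero] <- -Pi[!zero]
    dl_zm[!zero]  <- xp - mup * (xp + thp) / (thp + mup)
    dl_zth[!zero] <- thp * (digamma(xp + thp) - digamma(thp) +
                              log(thp) + 1 - log(thp + mup) -
                              (thp + xp) / (thp + mup))
  }
  sc <- -1 / (n * G)                    # NLL = -mean(logpmf)
  G_pi <- sc * dl_zpi; G_m <- sc * dl_zm; G_th <- sc * dl_zth

  # decoder
  dD  <- G_pi %*% t(p$W_pi) + G_m %*% t(p$W_m) + G_th %*% t(p$W_th)
  dZ2 <- dD * (fw$Z2 > 0)
  dB  <- dZ2 %*% t(p$W_d)
  dH  <- if (bottleneck_activation == "tanh") dB * (1 - fw$B^2) else dB * (fw$H > 0)

  # correlation penalty on the pre-activation bottleneck
  rho <- bottleneck_rho(fw$H)
  penalty <- 0
  if (lambda > 0 && ncol(fw$H) == 2L) {
    if (is.na(rho)) {
      if (warn_degenerate)
        warnf("a bottleneck neuron is constant across cells; correlation penalty set to 0")
    } else {
      penalty <- lambda * rho^2
      c1 <- fw$H[, 1] - mean(fw$H[, 1])
      c2 <- fw$H[, 2] - mean(fw$H[, 2])
      S11 <- sum(c1^2); S22 <- sum(c2^2); S12 <- sum(c1 * c2)
      dH[, 1] <- dH[, 1] + 2 * lambda * rho * (c2 / sqrt(S11 * S22) - rho * c1 / S11)
      dH[, 2] <- dH[, 2] + 2 * lambda * rho * (c1 / sqrt(S11 * S22) - rho * c2 / S22)
    }
  }
  if (is.na(rho)) rho <- 0

  dE  <- dH %*% t(p$W_b)
  dZ1 <- dE * (fw$Z1 > 0)

  grads <- list(
    W_e  = t(A) %*% dZ1,    b_e  = colSums(dZ1),
    W_b  = t(fw$E) %*% dH,  b_b  = colSums(dH),
    W_d  = t(fw$B) %*% dZ2, b_d  = colSums(dZ2),
    W_pi = t(fw$D) %*% G_pi, b_pi = colSums(G_pi),
    W_m  = t(fw$D) %*% G_m,  b_m  = colSums(G_m),
    W_th = t(fw$D) %*% G_th, b_th = colSums(G_th)
  )
  list(total = nll + penalty, nll = nll, penalty = penalty, rho = rho,
       grads = grads, fw = fw)
}

adam_init <- function(p) {
  list(m = lapply(p, function(x) x * 0), v = lapply(p, function(x) x * 0), t = 0L)
}

adam_step <- function(p, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    p[[nm]] <- p[[nm]] - lr * (state$m[[nm]] / bc1) /
      (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = p, state = state)
}
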