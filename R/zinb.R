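#' Zero-inflated negative binomial log-density
#'
#' Log probability mass of the ZINB distribution in the mean--dispersion
#' parameterization used throughout single-cell count modeling: a point mass
#' at zero with weight `pi` mixed with a negative binomial of mean `mu` and
#' dispersion `theta` (variance `mu + mu^2/theta`),
#' \deqn{NB(x;\mu,\theta)=\frac{\Gamma(x+\theta)}{\Gamma(\theta)\,\Gamma(x+1)}
#'   \left(\frac{\theta}{\theta+\mu}\right)^{\theta}
#'   \left(\frac{\mu}{\mu+\theta}\right)^{x}.}
#' `x` may be real-valued (counts after autoencoder denoising are not
#' integers); the factorial is generalized through the gamma function.
#' Evaluation is carried out in log space so extreme parameters do not
#' under/overflow.
#'
#' @param x observed counts, real, `>= 0`; recycled against the parameters.
#' @param pi dropout (zero-inflation) probability, in (0, 1).
#' @param mu negative binomial mean, `> 0`.
#' @param theta negative binomial dispersion, `> 0`.
#' @return numeric vector (or matrix, following `x`) of log densities, all
#'   `<= 0`.
#' @examples
#' zinb_logpmf(0, pi = 0.5, mu = 1, theta = 1)   # log(0.75)
#' zinb_logpmf(1, pi = 0.5, mu = 1, theta = 1)   # log(0.125)
#' @export
zinb_logpmf <- function(x, pi, mu, theta) {
  if (any(x < 0)) stopf("`x` must be non-negative")
  if (any(pi <= 0 | pi >= 1)) stopf("`pi` must lie strictly inside (0, 1)")
  if (any(mu <= 0)) stopf("`mu` must be positive")
  if (any(theta <= 0)) stopf("`theta` must be positive")

  # broadcast scalars against x while preserving x's shape
  n <- length(x)
  pi <- rep_len(pi, n); mu <- rep_len(mu, n); theta <- rep_len(theta, n)

  out <- numeric(n)
  lnb0 <- theta * (log(theta) - log(theta + mu))   # log NB(0; mu, theta)

  zero <- as.vector(x == 0)
  if (any(zero)) {
    # log(pi + (1-pi) * exp(lnb0)) via log-sum-exp
    a <- log(pi[zero])
    b <- log1p(-pi[zero]) + lnb0[zero]
    m <- pmax(a, b)
    out[zero] <- m + log(exp(a - m) + exp(b - m))
  }
  if (any(!zero)) {
    xp <- as.vector(x)[!zero]
    mup <- mu[!zero]; thp <- theta[!zero]
    lnb <- lgamma(xp + thp) - lgamma(thp) - lgamma(xp + 1) +
      thp * (log(thp) - log(thp + mup)) +
      xp * (log(mup) - log(mup + thp))
    out[!zero] <- log1p(-pi[!zero]) + lnb
  }
  if (is.matrix(x)) dim(out) <- dim(x)
  out
}
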