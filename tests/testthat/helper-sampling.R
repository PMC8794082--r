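# von Mises-Fisher sampler (Wood 1994 rejection scheme), used to generate
# data with known parameters for recovery tests. Independent of the
# package's fitting code, which never samples from the distribution.

rUnitSphere <- function(n, m) {
  z <- matrix(rnorm(n * m), n, m)
  z / sqrt(rowSums(z^2))
}

rVMF <- function(n, mu, kappa) {
  m <- length(mu)
  if (kappa == 0) return(rUnitSphere(n, m))
  b <- (-2 * kappa + sqrt(4 * kappa^2 + (m - 1)^2)) / (m - 1)
  x0 <- (1 - b) / (1 + b)
  c0 <- kappa * x0 + (m - 1) * log(1 - x0^2)
  w <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      z <- rbeta(1, (m - 1) / 2, (m - 1) / 2)
      wi <- (1 - (1 + b) * z) / (1 - (1 - b) * z)
      if (kappa * wi + (m - 1) * log(1 - x0 * wi) - c0 >= log(runif(1))) {
        w[i] <- wi
        break
      }
    }
  }
  v <- rUnitSphere(n, m - 1)
  x <- cbind(sqrt(pmax(1 - w^2, 0)) * v, w)
  # rotate the pole e_m onto mu with a Householder reflection
  e <- c(rep(0, m - 1), 1)
  u <- e - mu
  nu <- sqrt(sum(u^2))
  if (nu > 1e-12) {
    u <- u / nu
    x <- x - 2 * (x %*% u) %*% t(u)
  }
  x
}

# random orthogonal matrix (QR of a Gaussian matrix, sign-fixed)
randomRotation <- function(m) {
  qr0 <- qr(matrix(rnorm(m * m), m, m))
  q <- qr.Q(qr0)
  q %*% diag(sign(diag(qr.R(qr0))), m)
}

angleDeg <- function(a, b) {
  acos(min(max(sum(a * b) / sqrt(sum(a^2) * sum(b^2)), -1), 1)) * 180 / pi
}
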