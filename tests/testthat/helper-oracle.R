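# Independent proximal-gradient (ISTA) minimiser of the multinomial
# elastic-net objective, used as the oracle against the package's fitter.
# Deliberately shares no code with the implementation path.

enetObjectiveOracle <- function(X, yInd, B, b0, alpha, lambda) {
  eta <- sweep(X %*% t(B), 2, b0, `+`)
  eta <- eta - apply(eta, 1, max)
  logp <- eta - log(rowSums(exp(eta)))
  nll <- -sum(logp[yInd == 1]) / nrow(X)
  pen <- lambda * sum((1 - alpha) / 2 * B^2 + alpha * abs(B))
  nll + pen
}

istaMultinomial <- function(X, y, alpha, lambda, maxit = 200000,
                            tol = 1e-13) {
  y <- factor(y)
  K <- nlevels(y)
  n <- nrow(X)
  p <- ncol(X)
  yInd <- matrix(0, n, K)
  yInd[cbind(seq_len(n), as.integer(y))] <- 1
  B <- matrix(0, K, p)
  b0 <- rep(0, K)
  smooth <- function(B, b0) {
    eta <- sweep(X %*% t(B), 2, b0, `+`)
    eta <- eta - apply(eta, 1, max)
    logp <- eta - log(rowSums(exp(eta)))
    -sum(logp[yInd == 1]) / n + lambda * (1 - alpha) / 2 * sum(B^2)
  }
  gradient <- function(B, b0) {
    eta <- sweep(X %*% t(B), 2, b0, `+`)
    eta <- eta - apply(eta, 1, max)
    P <- exp(eta) / rowSums(exp(eta))
    D <- P - yInd
    list(B = t(D) %*% X / n + lambda * (1 - alpha) * B,
         b0 = colMeans(D))
  }
  softThresh <- function(z, t) sign(z) * pmax(abs(z) - t, 0)
  stepSize <- 1
  fOld <- smooth(B, b0) + lambda * alpha * sum(abs(B))
  for (it in seq_len(maxit)) {
    g <- gradient(B, b0)
    repeat {
      Bn <- softThresh(B - stepSize * g$B, stepSize * lambda * alpha)
      b0n <- b0 - stepSize * g$b0
      lhs <- smooth(Bn, b0n)
      rhs <- smooth(B, b0) + sum(g$B * (Bn - B)) + sum(g$b0 * (b0n - b0)) +
        (sum((Bn - B)^2) + sum((b0n - b0)^2)) / (2 * stepSize)
      if (lhs <= rhs + 1e-14 || stepSize < 1e-10) break
      stepSize <- stepSize / 2
    }
    B <- Bn
    b0 <- b0n
    fNew <- smooth(B, b0) + lambda * alpha * sum(abs(B))
    if (abs(fOld - fNew) < tol && it > 20) break
    fOld <- fNew
    stepSize <- min(stepSize * 1.5, 10)
  }
  list(B = B, b0 = b0, objective = fNew, yInd = yInd)
}
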