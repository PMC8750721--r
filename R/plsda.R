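# PLS-DA: univariate partial least squares (NIPALS PLS1) regression on a
# 0/1-coded class response, thresholded at 0.5. Written in-package; the
# deflation scheme is the classical one (orthogonal scores).

fit_plsda <- function(X, y, ncomp = 10) {
  X <- as.matrix(X)
  y01 <- as.numeric(y == "infested")
  n <- nrow(X); p <- ncol(X)
  ncomp <- min(ncomp, p, n - 1L)
  xm <- colMeans(X)
  ym <- mean(y01)
  E <- sweep(X, 2L, xm)
  f <- y01 - ym
  W <- matrix(0, p, ncomp)   # X weights
  P <- matrix(0, p, ncomp)   # X loadings
  qv <- numeric(ncomp)       # y loadings
  Tm <- matrix(0, n, ncomp)  # scores
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { ncomp <- a - 1L; break }
    w <- w / nw
    t_ <- drop(E %*% w)
    tt <- sum(t_^2)
    if (tt < 1e-12) { ncomp <- a - 1L; break }
    pvec <- drop(crossprod(E, t_)) / tt
    q <- sum(f * t_) / tt
    E <- E - tcrossprod(t_, pvec)
    f <- f - q * t_
    W[, a] <- w; P[, a] <- pvec; qv[a] <- q; Tm[, a] <- t_
  }
  cs_assert(ncomp >= 1, "PLS-DA found no usable latent variable",
            "calyxscan_degenerate_label_error")
  W <- W[, seq_len(ncomp), drop = FALSE]
  P <- P[, seq_len(ncomp), drop = FALSE]
  qv <- qv[seq_len(ncomp)]
  # Regression coefficients in the original X space:
  # B = W (P'W)^-1 q ; intercept from the means.
  B <- W %*% solve(crossprod(P, W), qv)
  list(coef = drop(B), intercept = ym - sum(xm * drop(B)), ncomp = ncomp,
       x_mean = xm, y_mean = ym)
}

predict_plsda <- function(fit, X) {
  score <- drop(as.matrix(X) %*% fit$coef) + fit$intercept
  ifelse(score > 0.5, "infested", "healthy")
}
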