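# Gaussian-process regression (Matern-5/2) and acquisition functions for
# the Bayesian-optimization loop. Inputs are scaled to [0,1]^d by the
# caller; outputs are standardized internally. Kept deliberately small:
# dense Cholesky algebra is ample at <= a few hundred evaluations.

matern52 <- function(D, ls) {
  r <- sqrt(5) * D / ls
  (1 + r + r^2 / 3) * exp(-r)
}

gp_dist <- function(A, B) {
  # Euclidean distance matrix
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * A %*% t(B)
  sqrt(pmax(d2, 0))
}

gp_fit <- function(X, y, noise_floor = 1e-8) {
  X <- as.matrix(X)
  mu <- mean(y); sdy <- sd(y)
  if (!is.finite(sdy) || sdy < 1e-12) sdy <- 1
  ys <- (y - mu) / sdy
  D <- gp_dist(X, X)
  nll <- function(par) {
    ls <- exp(par[1]); nug <- exp(par[2])
    K <- matern52(D, ls) + diag(nug + noise_floor, nrow(X))
    ch <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    a <- backsolve(ch, forwardsolve(t(ch), ys))
    0.5 * sum(ys * a) + sum(log(diag(ch)))
  }
  best <- NULL
  for (start in list(c(log(0.3), log(1e-4)), c(log(1), log(1e-2)),
                     c(log(0.1), log(1e-6)))) {
    op <- optim(start, nll, method = "L-BFGS-B",
                lower = c(log(0.01), log(1e-8)),
                upper = c(log(10), log(1)))
    if (is.null(best) || op$value < best$value) best <- op
  }
  ls <- exp(best$par[1]); nug <- exp(best$par[2])
  K <- matern52(D, ls) + diag(nug + noise_floor, nrow(X))
  ch <- chol(K)
  alpha <- backsolve(ch, forwardsolve(t(ch), ys))
  list(X = X, ch = ch, alpha = alpha, ls = ls, nug = nug,
       mu = mu, sdy = sdy)
}

gp_predict <- function(gp, Xnew) {
  Xnew <- as.matrix(Xnew)
  Ks <- matern52(gp_dist(Xnew, gp$X), gp$ls)
  m <- as.numeric(Ks %*% gp$alpha)
  v <- forwardsolve(t(gp$ch), t(Ks))
  s2 <- pmax(1 + gp$nug - colSums(v^2), 1e-12)
  list(mean = m * gp$sdy + gp$mu, sd = sqrt(s2) * gp$sdy)
}

acq_expected_improvement <- function(pred, ymin, xi = 1e-3) {
  z <- (ymin - pred$mean - xi) / pred$sd
  (ymin - pred$mean - xi) * pnorm(z) + pred$sd * dnorm(z)
}

acq_lower_confidence_bound <- function(pred, kappa = 2) {
  -(pred$mean - kappa * pred$sd) # larger is better, like EI
}
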