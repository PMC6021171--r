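# Two-state Gaussian-emission hidden Markov model: Baum-Welch on a
# single sequence plus Viterbi decoding. Small and self-contained; used
# for TIRF trace segmentation.

fitHmm2 <- function(x, means0 = c(0.2, 0.4), maxIter = 100,
                    tol = 1e-8, sdFloor = 1e-3) {
  n <- length(x)
  mu <- means0
  sg <- rep(max(sd(x) / 2, sdFloor), 2)
  A <- matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2, byrow = TRUE)
  pi0 <- c(0.5, 0.5)
  ll_old <- -Inf
  for (it in seq_len(maxIter)) {
    B <- cbind(dnorm(x, mu[1], sg[1]), dnorm(x, mu[2], sg[2]))
    B <- pmax(B, 1e-300)
    # scaled forward-backward
    alpha <- matrix(0, n, 2); beta <- matrix(0, n, 2)
    cscale <- numeric(n)
    a <- pi0 * B[1, ]; cscale[1] <- sum(a); alpha[1, ] <- a / cscale[1]
    for (t in 2:n) {
      a <- (alpha[t - 1, ] %*% A) * B[t, ]
      cscale[t] <- sum(a)
      alpha[t, ] <- a / cscale[t]
    }
    beta[n, ] <- 1
    for (t in (n - 1):1)
      beta[t, ] <- (A %*% (B[t + 1, ] * beta[t + 1, ])) / cscale[t + 1]
    gam <- alpha * beta
    gam <- gam / rowSums(gam)
    xi11 <- alpha[-n, 1] * A[1, 1] * B[-1, 1] * beta[-1, 1] / cscale[-1]
    xi12 <- alpha[-n, 1] * A[1, 2] * B[-1, 2] * beta[-1, 2] / cscale[-1]
    xi21 <- alpha[-n, 2] * A[2, 1] * B[-1, 1] * beta[-1, 1] / cscale[-1]
    xi22 <- alpha[-n, 2] * A[2, 2] * B[-1, 2] * beta[-1, 2] / cscale[-1]
    A <- matrix(c(sum(xi11), sum(xi12), sum(xi21), sum(xi22)), 2, 2,
                byrow = TRUE)
    A <- A / pmax(rowSums(A), 1e-300)
    pi0 <- gam[1, ]
    w <- colSums(gam)
    mu <- colSums(gam * x) / w
    sg <- sqrt(colSums(gam * (x - rep(mu, each = n))^2) / w)
    sg <- pmax(sg, sdFloor)
    ll <- sum(log(cscale))
    done <- abs(ll - ll_old) < tol * (1 + abs(ll))
    ll_old <- ll
    if (done) break
  }
  # keep state 1 = lower mean
  if (mu[1] > mu[2]) {
    mu <- rev(mu); sg <- rev(sg); pi0 <- rev(pi0)
    A <- A[2:1, 2:1]
  }
  list(mean = mu, sd = sg, trans = A, init = pi0, logLik = ll_old)
}

viterbi2 <- function(x, hmm) {
  n <- length(x)
  logB <- cbind(dnorm(x, hmm$mean[1], hmm$sd[1], log = TRUE),
                dnorm(x, hmm$mean[2], hmm$sd[2], log = TRUE))
  logA <- log(pmax(hmm$trans, 1e-300))
  d <- matrix(-Inf, n, 2); psi <- matrix(1L, n, 2)
  d[1, ] <- log(pmax(hmm$init, 1e-300)) + logB[1, ]
  for (t in 2:n) {
    for (s in 1:2) {
      v <- d[t - 1, ] + logA[, s]
      psi[t, s] <- which.max(v)
      d[t, s] <- max(v) + logB[t, s]
    }
  }
  path <- integer(n)
  path[n] <- which.max(d[n, ])
  for (t in (n - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  path
}
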