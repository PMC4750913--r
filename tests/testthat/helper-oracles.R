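# Independent scalar oracles for the EM updates: literal double-loop
# transcriptions of the mixture formulas, kept free of the package's
# vectorized code paths.

oracle_sqdist <- function(a, b) sum((a - b)^2)

# structure-weighted posterior, one scalar at a time
oracle_estep <- function(X, TY, Cvals, sigma2, omega) {
  n <- nrow(X)
  m <- nrow(TY)
  d <- ncol(X)
  P <- matrix(0, m, n)
  p_out <- numeric(n)
  for (i in seq_len(n)) {
    s_n <- 0
    for (k in seq_len(m)) s_n <- s_n + Cvals[i, k]
    den <- omega * s_n * (2 * pi * sigma2)^(d / 2) / ((1 - omega) * n)
    for (k in seq_len(m)) {
      den <- den + Cvals[i, k] * exp(-oracle_sqdist(X[i, ], TY[k, ]) /
                                       (2 * sigma2))
    }
    for (j in seq_len(m)) {
      P[j, i] <- Cvals[i, j] * exp(-oracle_sqdist(X[i, ], TY[j, ]) /
                                     (2 * sigma2)) / den
    }
    p_out[i] <- 1 - sum(P[, i])
  }
  list(P = P, P_outlier = p_out)
}

oracle_sigma2 <- function(P, X, TY, floor = 1e-8) {
  acc <- 0
  np <- 0
  for (i in seq_len(nrow(X))) {
    for (j in seq_len(nrow(TY))) {
      acc <- acc + P[j, i] * oracle_sqdist(X[i, ], TY[j, ])
      np <- np + P[j, i]
    }
  }
  max(acc / (ncol(X) * np), floor)
}

oracle_omega <- function(P, omega_old, t, n_scene) {
  omega_new <- 1 - sum(P) / n_scene
  out <- omega_old + (1 / t) * (omega_new - omega_old)
  min(max(out, 1e-6), 1 - 1e-6)
}

oracle_objective <- function(P, X, TY, sigma2, omega, lambda, G, W) {
  n <- nrow(X)
  d <- ncol(X)
  omega <- min(max(omega, 1e-6), 1 - 1e-6)
  acc <- 0
  np <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(nrow(TY))) {
      acc <- acc + P[j, i] * oracle_sqdist(X[i, ], TY[j, ])
      np <- np + P[j, i]
    }
  }
  reg <- 0
  GW <- G %*% W
  for (j in seq_len(nrow(W))) {
    for (c in seq_len(ncol(W))) reg <- reg + W[j, c] * GW[j, c]
  }
  acc / (2 * sigma2) + d * np / 2 * log(sigma2) -
    np * log(1 - omega) - (n - np) * log(omega) +
    lambda / 2 * reg
}

oracle_transform <- function(Y, G, W) {
  out <- Y
  for (i in seq_len(nrow(Y))) {
    for (j in seq_len(nrow(Y))) {
      out[i, ] <- out[i, ] + G[i, j] * W[j, ]
    }
  }
  out
}

# residual of the regularized kernel system for a candidate W
oracle_solve_residual <- function(W, G, P, X, Y, lambda, sigma2) {
  p1 <- rowSums(P)
  inv_p1 <- ifelse(p1 < 1e-10, 1e10, 1 / p1)
  A <- G + lambda * sigma2 * diag(inv_p1)
  rhs <- diag(inv_p1) %*% (P %*% X) - Y
  list(residual = norm(A %*% W - rhs, "F"), rhs_norm = norm(rhs, "F"))
}

# literal baseline CPD: plain-GMM posterior, variance update, kernel solve,
# in the engine's loop order but written independently
oracle_baseline_cpd <- function(X, Y, omega, lambda, beta, iters) {
  n <- nrow(X)
  m <- nrow(Y)
  d <- ncol(X)
  G <- matrix(0, m, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      G[i, j] <- exp(-oracle_sqdist(Y[i, ], Y[j, ]) / (2 * beta))
    }
  }
  sigma2 <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) sigma2 <- sigma2 + oracle_sqdist(X[i, ], Y[j, ])
  }
  sigma2 <- max(sigma2 / (d * n * m), 1e-8)
  TY <- Y
  sig_tr <- vector("list", iters)
  P_tr <- vector("list", iters)
  W_tr <- vector("list", iters)
  for (t in seq_len(iters)) {
    P <- matrix(0, m, n)
    for (i in seq_len(n)) {
      den <- omega * m * (2 * pi * sigma2)^(d / 2) / ((1 - omega) * n)
      for (k in seq_len(m)) {
        den <- den + exp(-oracle_sqdist(X[i, ], TY[k, ]) / (2 * sigma2))
      }
      for (j in seq_len(m)) {
        P[j, i] <- exp(-oracle_sqdist(X[i, ], TY[j, ]) / (2 * sigma2)) / den
      }
    }
    sigma2 <- oracle_sigma2(P, X, TY)
    p1 <- rowSums(P)
    inv_p1 <- ifelse(p1 < 1e-10, 1e10, 1 / p1)
    W <- solve(G + lambda * sigma2 * diag(inv_p1),
               diag(inv_p1) %*% (P %*% X) - Y)
    TY <- Y + G %*% W
    sig_tr[[t]] <- sigma2
    P_tr[[t]] <- P
    W_tr[[t]] <- W
  }
  list(sigma2 = unlist(sig_tr), P = P_tr, W = W_tr, TY = TY)
}

# small random EM instance: a jittered copy so posteriors are well-behaved
random_instance <- function(seed, n_max = 8L, m_max = 8L) {
  set.seed(seed)
  n <- sample(3:n_max, 1)
  m <- sample(2:m_max, 1)
  d <- 2L
  X <- matrix(rnorm(n * d), n, d)
  Y <- matrix(rnorm(m * d), m, d)
  Cvals <- matrix(runif(n * m, 0.05, 1), n, m)
  sigma2 <- runif(1, 0.2, 2)
  omega <- runif(1, 0, 0.8)
  list(X = X, Y = Y, Cvals = Cvals, sigma2 = sigma2, omega = omega,
       n = n, m = m)
}
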