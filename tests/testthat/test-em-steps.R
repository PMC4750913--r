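test_that("initialization follows the mean-squared-distance rule", {
  st <- cpd_initialize(rbind(c(0, 0)), rbind(c(3, 4)))
  expect_equal(st$sigma2, 12.5)
  expect_equal(st$TY, rbind(c(3, 4)))
  expect_true(all(st$W == 0))
  # degenerate coincident input clamps to the floor
  st0 <- cpd_initialize(rbind(c(0, 0)), rbind(c(0, 0)), sigma2_floor = 1e-8)
  expect_equal(st0$sigma2, 1e-8)
  expect_error(cpd_initialize(matrix(0, 2, 2), matrix(0, 2, 3)),
               class = "driftreg_invalid_input")
})

test_that("kernel matrix is symmetric with unit diagonal", {
  set.seed(3)
  G <- gaussian_kernel_matrix(matrix(rnorm(20), 10, 2), beta = 2)
  expect_equal(G, t(G))
  expect_equal(unname(diag(G)), rep(1, 10))
})

test_that("posteriors match a hand-evaluated two-point instance", {
  X <- rbind(c(0, 0), c(1, 0))
  TY <- rbind(c(0, 0), c(1, 0))
  sigma2 <- 0.5
  omega <- 0.1
  es <- cpd_estep(X, TY, uniform_cost_matrix(2, 2), sigma2, omega)
  # scalar arithmetic: e0 = exp(0), e1 = exp(-1/(2*0.5)) = exp(-1)
  u <- omega * 2 * (2 * pi * sigma2)^1 / ((1 - omega) * 2)
  den <- 1 + exp(-1) + u
  expect_equal(es$P[1, 1], 1 / den, tolerance = 1e-12)
  expect_equal(es$P[2, 1], exp(-1) / den, tolerance = 1e-12)
  expect_equal(es$P_outlier[1], 1 - (1 + exp(-1)) / den, tolerance = 1e-12)
  expect_equal(colSums(es$P) + es$P_outlier, c(1, 1), tolerance = 1e-12)
})

test_that("posterior edge cases: single component, zero omega, omega near 1", {
  X <- matrix(rnorm(10), 5, 2)
  es <- cpd_estep(X, rbind(c(0, 0)), uniform_cost_matrix(5, 1), 1, 0)
  expect_equal(unname(es$P[1, ]), rep(1, 5))
  expect_equal(unname(es$P_outlier), rep(0, 5))
  expect_error(cpd_estep(X, rbind(c(0, 0)), uniform_cost_matrix(5, 1), 1, 1),
               class = "driftreg_invalid_input")
})

test_that("EM updates match scalar brute-force oracles on random instances", {
  for (s in 1:30) {
    inst <- random_instance(s)
    C <- driftreg::uniform_cost_matrix(inst$n, inst$m)
    C$values <- inst$Cvals
    C$row_sums <- rowSums(inst$Cvals)
    es <- cpd_estep(inst$X, inst$Y, C, inst$sigma2, inst$omega)
    or <- oracle_estep(inst$X, inst$Y, inst$Cvals, inst$sigma2, inst$omega)
    expect_lt(max(abs(es$P - or$P)), 1e-12)
    expect_lt(max(abs(es$P_outlier - or$P_outlier)), 1e-12)
    expect_equal(cpd_update_sigma2(es$P, inst$X, inst$Y),
                 oracle_sigma2(es$P, inst$X, inst$Y), tolerance = 1e-12)
  }
})

test_that("outlier-ratio update follows the damped exact minimizer", {
  # t = 1 adopts omega_new fully; arithmetic of the damping at t = 2
  P_half <- matrix(0.3 / 4, 2, 2)  # NP = 0.3, N = 2 -> omega_new = 0.85
  expect_equal(cpd_update_omega(P_half, 0.2, t = 1, n_scene = 2), 0.85)
  # omega_old = 0.5 moving toward omega_new = 0.7 at t = 2 lands at 0.6
  P <- matrix(0.6 / 4, 2, 2)  # NP = 0.6, N = 2 -> omega_new = 0.7
  expect_equal(cpd_update_omega(P, 0.5, t = 2, n_scene = 2), 0.6)
  # full posterior mass: omega_new = 0, clamped just above zero
  P1 <- matrix(0.5, 2, 2)  # NP = 2 = N
  expect_equal(cpd_update_omega(P1, 0.4, t = 1, n_scene = 2), 1e-6)
  # random arithmetic against the oracle
  for (s in 1:20) {
    inst <- random_instance(s)
    es <- oracle_estep(inst$X, inst$Y, inst$Cvals, inst$sigma2, inst$omega)
    t <- sample(1:10, 1)
    expect_equal(cpd_update_omega(es$P, inst$omega, t, inst$n),
                 oracle_omega(es$P, inst$omega, t, inst$n),
                 tolerance = 1e-14)
  }
})

test_that("variance update handles exact fits and degenerate posteriors", {
  expect_equal(cpd_update_sigma2(matrix(1, 1, 1), rbind(c(0, 0)),
                                 rbind(c(3, 4))), 12.5)
  Y <- matrix(rnorm(8), 4, 2)
  expect_equal(cpd_update_sigma2(diag(4), Y, Y, floor = 1e-8), 1e-8)
  expect_error(cpd_update_sigma2(matrix(0, 4, 4), Y, Y),
               class = "driftreg_degenerate_posterior")
})

test_that("coefficient solve satisfies its linear system and fixed points", {
  for (s in 1:20) {
    inst <- random_instance(s)
    es <- oracle_estep(inst$X, inst$Y, inst$Cvals, inst$sigma2, inst$omega)
    G <- gaussian_kernel_matrix(inst$Y, beta = 2)
    lambda <- runif(1, 0.5, 4)
    W <- cpd_solve_coefficients(G, es$P, inst$X, inst$Y, lambda, inst$sigma2)
    res <- oracle_solve_residual(W, G, es$P, inst$X, inst$Y, lambda,
                                 inst$sigma2)
    expect_lt(res$residual, 1e-8 * max(res$rhs_norm, 1e-12))
  }
  # X = Y with identity pairing: zero right-hand side, zero displacement
  Y <- matrix(rnorm(12), 6, 2)
  G <- gaussian_kernel_matrix(Y)
  W0 <- cpd_solve_coefficients(G, diag(6), Y, Y, 2, 0.5)
  expect_lt(max(abs(W0)), 1e-12)
  expect_equal(cpd_transform(Y, G, W0), Y, tolerance = 1e-12)
})

test_that("with lambda ~ 0 each centroid moves to its posterior-weighted mean", {
  set.seed(4)
  X <- matrix(rnorm(8), 4, 2)
  Y <- matrix(rnorm(8), 4, 2)
  P <- matrix(runif(16, 0.1, 1), 4, 4)
  G <- gaussian_kernel_matrix(Y, beta = 5)
  W <- cpd_solve_coefficients(G, P, X, Y, lambda = 1e-12, sigma2 = 1)
  target <- diag(1 / rowSums(P)) %*% (P %*% X)
  expect_equal(cpd_transform(Y, G, W), target, tolerance = 1e-6)
})

test_that("transform equals the per-point kernel expansion", {
  for (s in 1:5) {
    set.seed(s)
    Y <- matrix(rnorm(10), 5, 2)
    G <- gaussian_kernel_matrix(Y)
    W <- matrix(rnorm(10), 5, 2)
    expect_equal(cpd_transform(Y, G, W), oracle_transform(Y, G, W),
                 tolerance = 1e-12)
  }
  # unit kernel moves the single point by exactly W
  expect_equal(cpd_transform(rbind(c(0, 0)), matrix(1, 1, 1),
                             rbind(c(2, 3))), rbind(c(2, 3)))
})

test_that("objective matches the scalar oracle and its closed forms", {
  for (s in 1:20) {
    inst <- random_instance(s)
    es <- oracle_estep(inst$X, inst$Y, inst$Cvals, inst$sigma2, inst$omega)
    G <- gaussian_kernel_matrix(inst$Y)
    W <- matrix(rnorm(inst$m * 2, sd = 0.3), inst$m, 2)
    TY <- inst$Y + G %*% W
    q <- cpd_objective(es$P, inst$X, TY, inst$sigma2, inst$omega, 2, G, W)
    qo <- oracle_objective(es$P, inst$X, TY, inst$sigma2, inst$omega, 2, G, W)
    expect_equal(q, qo, tolerance = 1e-12)
  }
  # zero-displacement perfect pairing: only the log-sigma2 and omega terms
  Y <- matrix(rnorm(6), 3, 2)
  W0 <- matrix(0, 3, 2)
  G <- gaussian_kernel_matrix(Y)
  q <- cpd_objective(diag(3), Y, Y, 1e-8, 0.5, 2, G, W0)
  expect_equal(q, 2 * 3 / 2 * log(1e-8) - 3 * log(0.5), tolerance = 1e-10)
})
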