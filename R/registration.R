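#' Low-level EM steps of the registration engine
#'
#' These functions expose the individual Expectation-Maximization updates of
#' the registration engine on plain matrices, mainly for testing and for
#' building custom loops; most users call [cpd_register()]. Conventions:
#' scene `X` is N x D, model (or its current transform) is M x D, the
#' posterior `P` is M x N with `P[m, n]` the probability that scene point n
#' was generated by mixture component m, and the structure weights come from a
#' [shape_cost_matrix()] or [uniform_cost_matrix()].
#'
#' `cpd_initialize()` builds the starting state: sigma2 is the mean squared
#' distance between all scene/model pairs divided by D, the kernel matrix is
#' G_ij = exp(-||y_i - y_j||^2 / (2 beta)), and the displacement coefficients
#' W start at zero (so the initial transform is the identity).
#'
#' `cpd_estep()` computes structure-weighted posteriors: component m gets
#' weight C_nm * exp(-||x_n - ty_m||^2 / (2 sigma2)); the uniform background
#' component contributes omega * S_n * (2 pi sigma2)^(D/2) / ((1 - omega) * N)
#' to the denominator, where S_n is the n-th row sum of the cost matrix. With
#' a uniform cost matrix (S_n = M) this is exactly the plain-CPD posterior.
#'
#' `cpd_update_sigma2()` is the M-step variance update
#' sigma2 = sum_{mn} P_mn ||x_n - ty_m||^2 / (D * NP), floored at `floor`.
#'
#' `cpd_update_omega()` damps the exact outlier-ratio minimizer
#' omega_new = 1 - NP / N through omega <- omega_old + alpha (omega_new -
#' omega_old) with learning ratio alpha = 1/t (t = 1 adopts omega_new fully).
#'
#' `cpd_solve_coefficients()` solves the regularized kernel system
#' (G + lambda sigma2 diag(P1)^-1) W = diag(P1)^-1 P X - Y for the
#' displacement coefficients; rows with vanishing posterior mass (P1 < 1e-10)
#' are guarded so those centroids follow the smoothness regularizer.
#'
#' `cpd_transform()` applies the displacement: T(Y, W) = Y + G W.
#'
#' `cpd_objective()` evaluates the penalized expected negative log-likelihood
#' Q = sum P ||x - ty||^2 / (2 sigma2) + D NP/2 log sigma2
#'   - NP log(1 - omega) - (N - NP) log omega + lambda/2 tr(W' G W),
#' with omega clamped away from {0, 1}.
#'
#' @param X,Y,TY Coordinate matrices (scene, model, transformed model).
#' @param C A `cost_matrix` (N x M).
#' @param sigma2 Isotropic variance of the Gaussian components.
#' @param omega Outlier (uniform-component) weight in \[0, 1).
#' @param P Posterior matrix (M x N).
#' @param floor Lower bound applied to the updated variance.
#' @param omega_old Previous outlier weight.
#' @param t 1-based iteration counter for the learning-ratio schedule.
#' @param n_scene Number of scene points N.
#' @param G Model kernel matrix (M x M).
#' @param lambda Smoothness regularization weight.
#' @param W Displacement coefficient matrix (M x D).
#' @param beta Gaussian kernel width of G.
#' @name cpd-steps
NULL

OMEGA_EPS <- 1e-6

clamp_omega <- function(omega) min(max(omega, OMEGA_EPS), 1 - OMEGA_EPS)

#' @rdname cpd-steps
#' @param sigma2_floor Lower bound kept on sigma2 throughout the run.
#' @return `cpd_initialize()`: a list (EM state) with elements `sigma2`,
#'   `omega`, `W`, `G`, `TY`, `t`.
#' @export
cpd_initialize <- function(X, Y, omega = 0.5, beta = 2,
                           sigma2_floor = 1e-8) {
  X <- as_point_matrix(X)
  Y <- as_point_matrix(Y)
  if (ncol(X) != ncol(Y)) {
    abort("scene and model must have the same dimension",
          class = "driftreg_invalid_input")
  }
  d <- ncol(X)
  sigma2 <- sum(sqdist(X, Y)) / (d * nrow(X) * nrow(Y))
  list(
    sigma2 = max(sigma2, sigma2_floor),
    omega = omega,
    W = matrix(0, nrow(Y), d),
    G = gaussian_kernel_matrix(Y, beta),
    TY = Y,
    t = 1L
  )
}

#' Gaussian kernel matrix of a point set
#'
#' G_ij = exp(-||y_i - y_j||^2 / (2 beta)); symmetric with unit diagonal.
#'
#' @inheritParams cpd-steps
#' @return M x M matrix.
#' @export
gaussian_kernel_matrix <- function(Y, beta = 2) {
  stopifnot(beta > 0)
  Y <- as_point_matrix(Y)
  g <- exp(-sqdist(Y, Y) / (2 * beta))
  (g + t(g)) / 2
}

#' @rdname cpd-steps
#' @return `cpd_estep()`: a list with `P` (M x N posterior matrix) and
#'   `P_outlier` (length-N vector), satisfying colSums(P) + P_outlier = 1.
#' @export
cpd_estep <- function(X, TY, C, sigma2, omega) {
  X <- as_point_matrix(X)
  TY <- as_point_matrix(TY)
  stopifnot(inherits(C, "cost_matrix"))
  if (sigma2 <= 0) abort("sigma2 must be positive")
  if (omega >= 1 || omega < 0) {
    abort("omega must lie in [0, 1)", class = "driftreg_invalid_input")
  }
  n <- nrow(X)
  m <- nrow(TY)
  d <- ncol(X)
  if (nrow(C$values) != n || ncol(C$values) != m) {
    abort("cost matrix shape does not match the point sets",
          class = "driftreg_invalid_input")
  }
  num <- C$values * exp(-sqdist(X, TY) / (2 * sigma2))     # N x M
  unif <- omega * C$row_sums * (2 * pi * sigma2)^(d / 2) / ((1 - omega) * n)
  den <- rowSums(num) + unif
  den[den <= 0] <- .Machine$double.xmin
  P <- t(num / den)                                         # M x N
  list(P = P, P_outlier = pmax(1 - colSums(P), 0))
}

#' @rdname cpd-steps
#' @return `cpd_update_sigma2()`: the updated scalar variance.
#' @export
cpd_update_sigma2 <- function(P, X, TY, floor = 1e-8) {
  X <- as_point_matrix(X)
  TY <- as_point_matrix(TY)
  np <- sum(P)
  if (np <= 0) {
    abort("all scene points classified as outliers (sum(P) = 0)",
          class = "driftreg_degenerate_posterior")
  }
  s2 <- sum(t(P) * sqdist(X, TY)) / (ncol(X) * np)
  max(s2, floor)
}

#' @rdname cpd-steps
#' @param alpha Optional fixed learning ratio; the default `NULL` uses the
#'   1/t schedule. `alpha = 0` freezes omega.
#' @return `cpd_update_omega()`: the updated outlier weight, clamped to
#'   (0, 1).
#' @export
cpd_update_omega <- function(P, omega_old, t, n_scene, alpha = NULL) {
  stopifnot(t >= 1)
  if (is.null(alpha)) alpha <- 1 / t
  omega_new <- 1 - sum(P) / n_scene
  clamp_omega(omega_old + alpha * (omega_new - omega_old))
}

#' @rdname cpd-steps
#' @return `cpd_solve_coefficients()`: the M x D coefficient matrix solving
#'   the regularized system; an error of class `driftreg_numerical_failure`
#'   if the guarded system is singular.
#' @export
cpd_solve_coefficients <- function(G, P, X, Y, lambda, sigma2) {
  X <- as_point_matrix(X)
  Y <- as_point_matrix(Y)
  p1 <- rowSums(P)
  inv_p1 <- ifelse(p1 < 1e-10, 1e10, 1 / p1)
  A <- G + lambda * sigma2 * diag(inv_p1, nrow = length(inv_p1))
  rhs <- inv_p1 * (P %*% X) - Y
  W <- tryCatch(
    solve(A, rhs),
    error = function(e) {
      abort(paste0("kernel system is singular: ", conditionMessage(e)),
            class = "driftreg_numerical_failure")
    }
  )
  W
}

#' @rdname cpd-steps
#' @return `cpd_transform()`: the transformed model points Y + G W.
#' @export
cpd_transform <- function(Y, G, W) {
  as_point_matrix(Y) + G %*% W
}

#' Penalized negative log-likelihood of the mixture
#'
#' The exact (not bounded) negative log-likelihood of the scene under the
#' structure-weighted mixture density
#' p(x_n) = omega / N + (1 - omega) / S_n * sum_m C_nm N(x_n; ty_m, sigma2),
#' plus the smoothness penalty lambda/2 tr(W' G W). Unlike the Q objective,
#' this quantity carries the full EM descent guarantee: with fixed structure
#' weights and frozen omega it is non-increasing across iterations.
#'
#' @inheritParams cpd-steps
#' @return Scalar penalized negative log-likelihood.
#' @export
cpd_neg_loglik <- function(X, TY, C, sigma2, omega, lambda, G, W) {
  X <- as_point_matrix(X)
  TY <- as_point_matrix(TY)
  n <- nrow(X)
  d <- ncol(X)
  omega <- clamp_omega(omega)
  gauss <- rowSums(C$values * exp(-sqdist(X, TY) / (2 * sigma2)))
  dens <- omega / n +
    (1 - omega) / (C$row_sums * (2 * pi * sigma2)^(d / 2)) * gauss
  -sum(log(pmax(dens, .Machine$double.xmin))) +
    lambda / 2 * sum(W * (G %*% W))
}

#' @rdname cpd-steps
#' @param NP Optional precomputed sum(P).
#' @return `cpd_objective()`: the scalar objective Q.
#' @export
cpd_objective <- function(P, X, TY, sigma2, omega, lambda, G, W,
                          NP = sum(P)) {
  X <- as_point_matrix(X)
  TY <- as_point_matrix(TY)
  n <- nrow(X)
  d <- ncol(X)
  omega <- clamp_omega(omega)
  data_term <- sum(t(P) * sqdist(X, TY)) / (2 * sigma2)
  data_term + d * NP / 2 * log(sigma2) -
    NP * log(1 - omega) - (n - NP) * log(omega) +
    lambda / 2 * sum(W * (G %*% W))
}

#' Register two point sets by structure-informed Coherent Point Drift
#'
#' Aligns a model point set onto a scene point set with a Gaussian-mixture EM
#' loop. The model points act as mixture centroids displaced by a smooth
#' kernel field, T(Y) = Y + G W; a uniform background component with mixing
#' weight omega absorbs outliers. Two improvements over plain CPD are on by
#' default: mixture memberships are weighted by shape-context similarity
#' (`structure = TRUE`), and omega is re-estimated each iteration under a 1/t
#' learning-rate schedule (`auto_omega = TRUE`). With both switched off the
#' engine is exactly the baseline non-rigid CPD algorithm.
#'
#' Both sets are internally translated to zero mean and scaled to unit RMS
#' radius; the aligned model is mapped back into the scene's original frame on
#' output. Shape-context descriptors are computed once from the initial sets
#' and the cost matrix is held fixed across iterations.
#'
#' @param scene Scene point set X (data frame or matrix, N x D): the data the
#'   model is aligned onto.
#' @param model Model point set Y (M x D): the mixture centroids to deform.
#' @param omega0 Initial outlier ratio in \[0, 1). Default 0.5.
#' @param lambda Smoothness regularization weight (> 0). Default 2.
#' @param beta Width of the Gaussian kernel defining the displacement field.
#'   Default 2 (normalized coordinates).
#' @param gamma Shape-context cost bandwidth. Default 0.1.
#' @param max_iter Iteration cap. Default 100.
#' @param tol Relative objective-change stopping tolerance. Default 1e-8.
#' @param structure Use shape-context weights? If `FALSE` (or the sets are not
#'   2-D, in which case a warning is issued) a uniform cost matrix is used.
#' @param auto_omega Re-estimate omega each iteration? `FALSE` freezes it at
#'   `omega0` (the plain-CPD behaviour).
#' @param normalize Pre-normalize both sets (zero mean, unit RMS radius)?
#'   Default `TRUE`; turn off when feeding already-normalized coordinates.
#' @param sigma2_floor Lower bound on the mixture variance. Default 1e-8.
#' @param n_radial,n_angular Shape-context binning.
#' @return An object of class `cpd_fit` with elements:
#'   \describe{
#'     \item{aligned}{tibble of transformed model points, in scene
#'       coordinates.}
#'     \item{correspondence}{tibble with one row per scene point:
#'       `scene`, `model` (NA for outliers), `posterior`, `outlier_posterior`.}
#'     \item{P, P_outlier}{final posterior matrix (M x N) and outlier vector.}
#'     \item{traces}{tibble with per-iteration `iter`, `Q`, `sigma2`, `omega`,
#'       and `nll` (the penalized negative log-likelihood of
#'       [cpd_neg_loglik()]).}
#'     \item{sigma2, omega, n_iter, converged}{final EM quantities.}
#'     \item{config}{the parameters the fit was run with.}
#'   }
#' @examples
#' y <- make_template("fishlike", 60)
#' x <- add_noise(y, 0.02, seed = 1)
#' fit <- cpd_register(x, y, max_iter = 30)
#' glance(fit)
#' @export
cpd_register <- function(scene, model,
                         omega0 = 0.5, lambda = 2, beta = 2, gamma = 0.1,
                         max_iter = 100L, tol = 1e-8,
                         structure = TRUE, auto_omega = TRUE,
                         normalize = TRUE, sigma2_floor = 1e-8,
                         n_radial = 5L, n_angular = 12L) {
  X0 <- as_point_matrix(scene)
  Y0 <- as_point_matrix(model)
  if (ncol(X0) != ncol(Y0)) {
    abort("scene and model must have the same dimension",
          class = "driftreg_invalid_input")
  }
  stopifnot(omega0 >= 0, omega0 < 1, lambda > 0, beta > 0, gamma > 0,
            max_iter >= 1, tol > 0)
  d <- ncol(X0)
  n <- nrow(X0)
  m <- nrow(Y0)

  if (normalize) {
    nx <- normalize_points(X0)
    ny <- normalize_points(Y0)
    X <- nx$points
    Y <- ny$points
  } else {
    X <- X0
    Y <- Y0
  }

  if (structure && d != 2L) {
    warn("shape contexts are 2-D only; falling back to a uniform cost matrix")
    structure <- FALSE
  }
  C <- if (structure) {
    shape_cost_matrix(shape_context(X, n_radial, n_angular),
                      shape_context(Y, n_radial, n_angular),
                      gamma = gamma)
  } else {
    uniform_cost_matrix(n, m)
  }

  state <- cpd_initialize(X, Y, omega = clamp_omega(omega0), beta = beta,
                          sigma2_floor = sigma2_floor)
  q_trace <- s2_trace <- om_trace <- nll_trace <- numeric(0)
  q_prev <- NA_real_
  converged <- FALSE
  es <- NULL

  for (t in seq_len(max_iter)) {
    es <- cpd_estep(X, state$TY, C, state$sigma2, state$omega)
    state$sigma2 <- cpd_update_sigma2(es$P, X, state$TY, floor = sigma2_floor)
    if (auto_omega) {
      state$omega <- cpd_update_omega(es$P, state$omega, t, n)
    }
    state$W <- cpd_solve_coefficients(state$G, es$P, X, Y, lambda,
                                      state$sigma2)
    state$TY <- cpd_transform(Y, state$G, state$W)
    q <- cpd_objective(es$P, X, state$TY, state$sigma2, state$omega,
                       lambda, state$G, state$W)
    q_trace <- c(q_trace, q)
    s2_trace <- c(s2_trace, state$sigma2)
    om_trace <- c(om_trace, state$omega)
    nll_trace <- c(nll_trace, cpd_neg_loglik(X, state$TY, C, state$sigma2,
                                             state$omega, lambda, state$G,
                                             state$W))
    state$t <- t
    if (!is.na(q_prev) && abs(q - q_prev) <= tol * (abs(q) + tol)) {
      converged <- TRUE
      break
    }
    q_prev <- q
  }

  aligned_norm <- state$TY
  aligned <- if (normalize) {
    denormalize_points(aligned_norm, nx$center, nx$scale)
  } else {
    aligned_norm
  }

  corr <- extract_correspondences(es$P, es$P_outlier)

  # NB: base::structure, the `structure` argument shadows it in this scope
  base::structure(
    list(
      aligned = as_point_tibble(aligned),
      correspondence = corr,
      P = es$P,
      P_outlier = es$P_outlier,
      traces = tibble::tibble(iter = seq_along(q_trace), Q = q_trace,
                              sigma2 = s2_trace, omega = om_trace,
                              nll = nll_trace),
      sigma2 = state$sigma2,
      omega = state$omega,
      W = state$W,
      n_iter = state$t,
      converged = converged,
      scene = as_point_tibble(X0),
      model = as_point_tibble(Y0),
      config = list(omega0 = omega0, lambda = lambda, beta = beta,
                    gamma = gamma, max_iter = max_iter, tol = tol,
                    structure = structure, auto_omega = auto_omega,
                    normalize = normalize, sigma2_floor = sigma2_floor,
                    n_radial = n_radial, n_angular = n_angular)
    ),
    class = "cpd_fit"
  )
}

# hard correspondence for reporting: scene point n pairs with its posterior
# argmax unless the outlier component dominates
extract_correspondences <- function(P, P_outlier) {
  n <- ncol(P)
  best <- apply(P, 2L, which.max)
  best_post <- P[cbind(best, seq_len(n))]
  is_out <- best_post <= P_outlier
  tibble::tibble(
    scene = seq_len(n),
    model = ifelse(is_out, NA_integer_, best),
    posterior = best_post,
    outlier_posterior = P_outlier
  )
}

#' @export
print.cpd_fit <- function(x, ...) {
  cat(sprintf(
    "<cpd_fit: %d scene / %d model points, %d iterations%s>\n",
    nrow(x$scene), nrow(x$model), x$n_iter,
    if (x$converged) " (converged)" else ""
  ))
  cat(sprintf("  sigma2 = %.4g, omega = %.4f, matched %d/%d scene points\n",
              x$sigma2, x$omega,
              sum(!is.na(x$correspondence$model)), nrow(x$scene)))
  invisible(x)
}
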