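#' Log-polar shape-context descriptors
#'
#' Computes, for every point of a 2-D set, the shape-context histogram of
#' Belongie et al.: the log-polar distribution of all other points around it.
#' Radii are normalized by the mean pairwise distance of the set, so the
#' descriptor is scale invariant; angles are measured relative to the
#' direction from the point to the mass centre of the shape, so it is rotation
#' invariant; and relative positions make it translation invariant.
#'
#' Radial bins are log-spaced between 0.125 and 2.0 mean-distance units
#' (the originating convention). Points falling outside the radial range are
#' clamped into the nearest (inner/outer) radial bin so that every raw
#' histogram counts all P-1 other points.
#'
#' @param points A 2-D point set (data frame or matrix with two numeric
#'   columns), at least 3 points.
#' @param n_radial,n_angular Number of log-radial and angular bins
#'   (K = `n_radial * n_angular` histogram entries per point).
#' @return An object of class `shape_context`: a list with `histograms`
#'   (P x K matrix of raw counts, each row summing to P-1), `bin_edges_radial`
#'   (length `n_radial + 1`, in mean-distance units), `bin_edges_angular`
#'   (length `n_angular + 1`, radians), and `reference_axis` (P x 2 matrix of
#'   unit vectors toward the mass centre).
#' @examples
#' ring <- make_template("ring", 40)
#' sc <- shape_context(ring)
#' dim(sc$histograms)
#' @seealso [shape_cost_matrix()]
#' @export
shape_context <- function(points, n_radial = 5L, n_angular = 12L) {
  m <- as_point_matrix(points)
  if (ncol(m) != 2L) {
    abort("shape contexts are defined for 2-D point sets only",
          class = "driftreg_unsupported_dimension")
  }
  if (nrow(m) < 3L) {
    abort("at least 3 points are required for a shape context",
          class = "driftreg_invalid_input")
  }
  p <- nrow(m)
  stopifnot(n_radial >= 1L, n_angular >= 1L)

  center <- colMeans(m)
  mean_dist <- mean(stats::dist(m))
  if (!is.finite(mean_dist) || mean_dist <= 0) {
    abort("degenerate point set: all points coincide",
          class = "driftreg_invalid_input")
  }

  r_edges <- exp(seq(log(0.125), log(2), length.out = n_radial + 1L))
  a_edges <- seq(0, 2 * pi, length.out = n_angular + 1L)
  k <- n_radial * n_angular

  # reference axis: unit vector from each point toward the mass centre;
  # a point sitting on the mass centre falls back to the global +x axis
  axis_vec <- sweep(-m, 2L, center, "+")
  axis_norm <- sqrt(rowSums(axis_vec^2))
  degen <- axis_norm < 1e-12
  if (any(degen)) {
    axis_vec[degen, ] <- matrix(c(1, 0), sum(degen), 2L, byrow = TRUE)
    axis_norm[degen] <- 1
  }
  axis_vec <- axis_vec / axis_norm
  axis_angle <- atan2(axis_vec[, 2L], axis_vec[, 1L])

  hist_mat <- matrix(0, p, k)
  log_edges <- log(r_edges)
  for (i in seq_len(p)) {
    rel <- sweep(m[-i, , drop = FALSE], 2L, m[i, ])
    r <- sqrt(rowSums(rel^2)) / mean_dist
    theta <- (atan2(rel[, 2L], rel[, 1L]) - axis_angle[i]) %% (2 * pi)
    # the 1e-9 snap makes points lying exactly on a bin edge (symmetric
    # configurations) bin identically regardless of rounding direction
    rbin <- findInterval(log(pmax(r, .Machine$double.xmin)) + 1e-9, log_edges,
                         all.inside = TRUE)
    rbin <- pmin(pmax(rbin, 1L), n_radial)
    abin <- pmin(floor(((theta + 1e-9) %% (2 * pi)) /
                         (2 * pi / n_angular)) + 1L, n_angular)
    idx <- (rbin - 1L) * n_angular + abin
    tab <- tabulate(idx, nbins = k)
    hist_mat[i, ] <- tab
  }

  structure(
    list(histograms = hist_mat,
         bin_edges_radial = r_edges,
         bin_edges_angular = a_edges,
         reference_axis = axis_vec,
         n_radial = as.integer(n_radial),
         n_angular = as.integer(n_angular)),
    class = "shape_context"
  )
}

#' @export
print.shape_context <- function(x, ...) {
  cat(sprintf("<shape_context: %d points, %d x %d bins>\n",
              nrow(x$histograms), x$n_radial, x$n_angular))
  invisible(x)
}

#' Shape-context matching-cost matrix
#'
#' Converts the chi-squared distance between two shape-context histograms into
#' a similarity weight C_nm = exp(-chi2_nm / (2 gamma)), where
#' chi2_nm = sum_k (h_n(k) - h_m(k))^2 / (h_n(k) + h_m(k)) over the K bins
#' (empty-vs-empty bins contribute 0). Histograms are normalized to sum 1
#' before comparison so that sets of different cardinality are comparable.
#' Identical histograms give cost exactly 1; all entries lie in (0, 1].
#'
#' @param desc_scene,desc_model `shape_context` objects built with identical
#'   binning, for the scene (N points) and model (M points) sets.
#' @param gamma Positive cost bandwidth; larger values flatten the weights
#'   toward 1. Default 0.1.
#' @return An object of class `cost_matrix`: list with `values` (N x M matrix
#'   in (0, 1]), `row_sums` (length-N vector S_n = sum_m C_nm), and `gamma`.
#' @examples
#' a <- shape_context(make_template("ring", 30))
#' cm <- shape_cost_matrix(a, a)
#' range(diag(cm$values))
#' @export
shape_cost_matrix <- function(desc_scene, desc_model, gamma = 0.1) {
  stopifnot(inherits(desc_scene, "shape_context"),
            inherits(desc_model, "shape_context"))
  if (gamma <= 0) abort("gamma must be positive")
  if (desc_scene$n_radial != desc_model$n_radial ||
      desc_scene$n_angular != desc_model$n_angular) {
    abort("descriptor sets use different binning",
          class = "driftreg_binning_mismatch")
  }
  hn <- normalize_histograms(desc_scene$histograms)
  hm <- normalize_histograms(desc_model$histograms)
  chi2 <- chi2_histogram_distance(hn, hm)
  values <- exp(-chi2 / (2 * gamma))
  new_cost_matrix(values, gamma)
}

normalize_histograms <- function(h) {
  s <- rowSums(h)
  s[s <= 0] <- 1
  h / s
}

# pairwise chi-squared statistic between rows of hn (N x K) and hm (M x K)
chi2_histogram_distance <- function(hn, hm) {
  n <- nrow(hn)
  m <- nrow(hm)
  chi2 <- matrix(0, n, m)
  for (k in seq_len(ncol(hn))) {
    num <- outer(hn[, k], hm[, k], "-")^2
    den <- outer(hn[, k], hm[, k], "+")
    nz <- den > 0
    if (any(nz)) chi2[nz] <- chi2[nz] + num[nz] / den[nz]
  }
  chi2
}

new_cost_matrix <- function(values, gamma = NA_real_) {
  structure(
    list(values = values, row_sums = rowSums(values), gamma = gamma),
    class = "cost_matrix"
  )
}

#' Uniform (structure-free) cost matrix
#'
#' The all-ones cost matrix under which the structure-weighted E-step reduces
#' exactly to plain CPD (every row sum S_n equals M).
#'
#' @param n_scene,n_model Number of scene and model points.
#' @return A `cost_matrix` with all entries 1.
#' @export
uniform_cost_matrix <- function(n_scene, n_model) {
  new_cost_matrix(matrix(1, n_scene, n_model))
}

#' @export
print.cost_matrix <- function(x, ...) {
  cat(sprintf("<cost_matrix: %d x %d, gamma = %s, range [%.3g, %.3g]>\n",
              nrow(x$values), ncol(x$values),
              format(x$gamma), min(x$values), max(x$values)))
  invisible(x)
}
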