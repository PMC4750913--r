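#' Coerce a point set to a coordinate matrix
#'
#' Point sets travel through the package as tibbles with one point per row and
#' one numeric column per coordinate (conventionally `x`, `y`). Internally all
#' arithmetic is done on plain numeric matrices; this pair of helpers converts
#' between the two representations.
#'
#' @param points A data frame of numeric columns, or a numeric matrix, one
#'   point per row.
#' @return `as_point_matrix()` returns a numeric matrix; `as_point_tibble()`
#'   returns a tibble with columns `x`, `y` (and `z`, ... for higher
#'   dimensions).
#' @examples
#' as_point_matrix(tibble::tibble(x = 1:3, y = 0))
#' as_point_tibble(matrix(rnorm(8), ncol = 2))
#' @export
as_point_matrix <- function(points) {
  if (is.matrix(points)) {
    storage.mode(points) <- "double"
    return(points)
  }
  if (is.data.frame(points)) {
    num <- vapply(points, is.numeric, logical(1))
    if (!all(num)) {
      abort("all point-set columns must be numeric")
    }
    if (ncol(points) < 1L || nrow(points) < 1L) {
      abort("point set must have at least one point and one coordinate")
    }
    return(unname(as.matrix(points)))
  }
  abort("a point set must be a data frame or a numeric matrix")
}

#' @rdname as_point_matrix
#' @export
as_point_tibble <- function(points) {
  m <- as_point_matrix(points)
  nm <- c("x", "y", "z")
  d <- ncol(m)
  cols <- if (d <= 3L) nm[seq_len(d)] else paste0("v", seq_len(d))
  colnames(m) <- cols
  tibble::as_tibble(m)
}

#' Centre and scale a point set to unit RMS radius
#'
#' Registration runs on normalized coordinates: each set is translated to zero
#' mean and scaled so the root-mean-square distance of its points from the
#' origin is 1. This makes the regularization weight, kernel width, and
#' degradation levels comparable across shapes of different extent.
#'
#' @param m Numeric matrix, one point per row.
#' @return A list with `points` (the normalized matrix), `center` (length-D
#'   mean vector), and `scale` (positive scalar).
#' @keywords internal
normalize_points <- function(m) {
  center <- colMeans(m)
  centred <- sweep(m, 2L, center)
  scale <- sqrt(mean(rowSums(centred^2)))
  if (!is.finite(scale) || scale <= 0) scale <- 1
  list(points = centred / scale, center = center, scale = scale)
}

denormalize_points <- function(m, center, scale) {
  sweep(m * scale, 2L, center, "+")
}

#' Squared Euclidean distance matrix between two point sets
#'
#' @param a,b Numeric matrices with the same number of columns.
#' @return `nrow(a)` x `nrow(b)` matrix of squared distances.
#' @keywords internal
sqdist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  pmax(d2, 0)
}
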