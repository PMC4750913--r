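#' Tidy a registration fit
#'
#' `tidy()` returns the hard correspondence table (one row per scene point;
#' `model` is NA where the outlier component dominates). `glance()` returns a
#' one-row summary of the fit. `augment()` returns the scene points with
#' their matched aligned model coordinates and posteriors bound on.
#'
#' @param x A `cpd_fit` from [cpd_register()].
#' @param ... Unused.
#' @return A tibble.
#' @examples
#' y <- make_template("ring", 40)
#' fit <- cpd_register(y, y, max_iter = 10)
#' glance(fit)
#' head(tidy(fit))
#' @method tidy cpd_fit
#' @export
tidy.cpd_fit <- function(x, ...) {
  x$correspondence
}

#' @rdname tidy.cpd_fit
#' @method glance cpd_fit
#' @export
glance.cpd_fit <- function(x, ...) {
  tibble::tibble(
    n_scene = nrow(x$scene),
    n_model = nrow(x$model),
    n_iter = x$n_iter,
    converged = x$converged,
    sigma2 = x$sigma2,
    omega = x$omega,
    Q = x$traces$Q[x$n_iter],
    n_matched = sum(!is.na(x$correspondence$model))
  )
}

#' @rdname tidy.cpd_fit
#' @param data Optional scene data to augment; defaults to the scene the fit
#'   was run on.
#' @method augment cpd_fit
#' @export
augment.cpd_fit <- function(x, data = NULL, ...) {
  scene <- if (is.null(data)) x$scene else as_point_tibble(data)
  corr <- x$correspondence
  al <- as_point_matrix(x$aligned)
  matched <- !is.na(corr$model)
  idx <- ifelse(matched, corr$model, 1L)
  out <- dplyr::bind_cols(scene, corr[, c("model", "posterior")])
  out$.aligned_x <- ifelse(matched, al[idx, 1L], NA_real_)
  out$.aligned_y <- ifelse(matched, al[idx, 2L], NA_real_)
  out$.outlier <- !matched
  out
}

#' Plot a registration fit
#'
#' `type = "alignment"` overlays the scene (circles), initial model
#' (crosses), and aligned model (filled triangles), with segments joining
#' matched pairs. `type = "trace"` shows the per-iteration objective,
#' variance, and outlier-ratio diagnostics.
#'
#' @param object A `cpd_fit`.
#' @param type `"alignment"` or `"trace"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cpd_fit
#' @export
autoplot.cpd_fit <- function(object, type = c("alignment", "trace"), ...) {
  type <- match.arg(type)
  if (type == "trace") {
    df <- tidyr::pivot_longer(object$traces, -"iter",
                              names_to = "quantity", values_to = "value")
    return(
      ggplot2::ggplot(df, ggplot2::aes(.data$iter, .data$value)) +
        ggplot2::geom_line() +
        ggplot2::facet_wrap(~quantity, scales = "free_y") +
        ggplot2::labs(x = "iteration", y = NULL,
                      title = "EM diagnostics")
    )
  }
  aug <- augment(object)
  layers <- list(
    ggplot2::geom_point(data = object$scene,
                        ggplot2::aes(.data$x, .data$y, colour = "scene"),
                        shape = 1),
    ggplot2::geom_point(data = object$model,
                        ggplot2::aes(.data$x, .data$y, colour = "model"),
                        shape = 3),
    ggplot2::geom_point(data = object$aligned,
                        ggplot2::aes(.data$x, .data$y, colour = "aligned"),
                        shape = 17, size = 1.5),
    ggplot2::geom_segment(
      data = aug[!aug$.outlier, ],
      ggplot2::aes(.data$x, .data$y,
                   xend = .data$.aligned_x, yend = .data$.aligned_y),
      colour = "darkgreen", alpha = 0.4
    )
  )
  ggplot2::ggplot() + layers +
    ggplot2::scale_colour_manual(
      values = c(scene = "red", model = "blue", aligned = "black"),
      name = NULL
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x", y = "y", title = "Point-set alignment")
}

#' Plot a benchmark case
#'
#' @param object A `benchmark_case`.
#' @param ... Unused.
#' @return A ggplot object showing model and scene point sets.
#' @method autoplot benchmark_case
#' @export
autoplot.benchmark_case <- function(object, ...) {
  df <- dplyr::bind_rows(
    dplyr::mutate(object$scene, set = "scene"),
    dplyr::mutate(object$model, set = "model")
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   colour = .data$set,
                                   shape = .data$set)) +
    ggplot2::geom_point() +
    ggplot2::scale_shape_manual(values = c(scene = 1, model = 3)) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s, level %g",
                                  object$spec$kind, object$spec$level))
}

#' Plot a degradation sweep
#'
#' Error-bar plot of per-level mean registration RMSE (+/- one standard
#' deviation) for the structure-informed method and baseline CPD.
#'
#' @param sweep Output of [degradation_sweep()].
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(.data$level, .data$mean_rmse,
                                      colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = pmax(.data$mean_rmse - .data$sd_rmse, 0),
                   ymax = .data$mean_rmse + .data$sd_rmse)
    ) +
    ggplot2::labs(x = "degradation level", y = "RMSE (normalized units)",
                  title = unique(sweep$kind))
}
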