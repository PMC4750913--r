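#' Degradation sweep: full method vs baseline CPD
#'
#' Runs the benchmark protocol at a series of degradation levels: for each
#' level and trial a synthetic case is generated, registered with both the
#' structure-informed engine (shape-context weights + automatic outlier
#' ratio) and baseline CPD (uniform weights, frozen outlier ratio), and the
#' point RMSE against ground truth is recorded. Per-level error means and
#' standard deviations are returned for each method. Unless `omega0` is
#' given, each level uses the benchmark initial outlier ratio of
#' [default_omega0()]; both methods always start from the same value.
#'
#' @param kind Degradation kind (see [make_benchmark_case()]).
#' @param levels Numeric vector of degradation levels.
#' @param trials Cases per level.
#' @param template,n_points Template passed to the generator.
#' @param seed Master seed; trial t at level i uses a sub-seed derived from it.
#' @param omega0 Optional initial outlier ratio(s): a scalar or one value per
#'   level. `NULL` uses the benchmark defaults.
#' @param max_iter,... Passed to [cpd_register()].
#' @return A tibble with one row per (level, method): columns `kind`, `level`,
#'   `method` (`"structure"`/`"baseline"`), `omega0`, `mean_rmse`, `sd_rmse`,
#'   `trials`.
#' @export
degradation_sweep <- function(kind, levels, trials = 5L,
                              template = "fishlike", n_points = 98L,
                              seed = 0L, omega0 = NULL, max_iter = 100L,
                              ...) {
  if (!is.null(omega0)) {
    omega0 <- rep_len(omega0, length(levels))
  }
  res <- purrr::imap(levels, function(level, i) {
    om <- if (is.null(omega0)) default_omega0(kind, level) else omega0[i]
    purrr::map(seq_len(trials), function(tr) {
      case_seed <- (as.integer(seed) %% 100003L) * 10007L + i * 101L + tr
      case <- make_benchmark_case(kind, level, template = template,
                                  n_points = n_points, seed = case_seed)
      one <- function(structure, auto) {
        fit <- cpd_register(case$scene, case$model, omega0 = om,
                            structure = structure, auto_omega = auto,
                            max_iter = max_iter, ...)
        rmse_points(fit$aligned, case$scene, case$truth)
      }
      tibble::tibble(
        kind = kind, level = level, omega0 = om, trial = tr,
        method = c("structure", "baseline"),
        rmse = c(one(TRUE, TRUE), one(FALSE, FALSE))
      )
    })
  })
  dplyr::bind_rows(res) |>
    dplyr::group_by(.data$kind, .data$level, .data$method, .data$omega0) |>
    dplyr::summarise(mean_rmse = mean(.data$rmse),
                     sd_rmse = stats::sd(.data$rmse),
                     trials = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$level, .data$method)
}

#' Initial outlier-ratio sweep
#'
#' Registers the same case from a range of initial outlier ratios and
#' collects the per-iteration omega traces, to examine whether the
#' automatically estimated ratio converges to a common value regardless of
#' its initialization.
#'
#' @param case A `benchmark_case` (or any list with `scene` and `model`).
#' @param omega0 Initial ratios to try.
#' @param max_iter,... Passed to [cpd_register()].
#' @return A tibble in long form: `omega0`, `iter`, `omega`, `final`
#'   (the run's final omega, repeated along its trace).
#' @export
omega_sweep <- function(case, omega0 = c(0.1, 0.3, 0.5, 0.7, 0.9),
                        max_iter = 100L, ...) {
  purrr::map(omega0, function(om) {
    fit <- cpd_register(case$scene, case$model, omega0 = om,
                        max_iter = max_iter, ...)
    dplyr::mutate(fit$traces[, c("iter", "omega")],
                  omega0 = om, final = fit$omega)
  }) |>
    dplyr::bind_rows() |>
    dplyr::select("omega0", "iter", "omega", "final")
}
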