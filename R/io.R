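#' Read and write plain-text point files
#'
#' One point per row, coordinates separated by whitespace or commas, optional
#' `#` comment lines. Dimension is inferred from the column count; the
#' round-trip preserves 12 significant digits.
#'
#' @param path File path.
#' @param points Point set to write.
#' @return `read_points()` returns a tibble of coordinates; `write_points()`
#'   invisibly returns `path`.
#' @export
read_points <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("cannot read point file '%s'", path),
          class = "driftreg_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) {
    abort(sprintf("'%s' contains no data rows", path),
          class = "driftreg_parse_error")
  }
  toks <- strsplit(trimws(lines[idx]), "[,[:space:]]+")
  ncols <- lengths(toks)
  if (length(unique(ncols)) != 1L) {
    bad <- idx[which(ncols != ncols[1])[1]]
    abort(sprintf("ragged row in '%s' at line %d (expected %d columns)",
                  path, bad, ncols[1]),
          class = "driftreg_parse_error")
  }
  vals <- suppressWarnings(lapply(toks, as.numeric))
  nas <- vapply(vals, anyNA, logical(1))
  if (any(nas)) {
    abort(sprintf("non-numeric token in '%s' at line %d",
                  path, idx[which(nas)[1]]),
          class = "driftreg_parse_error")
  }
  as_point_tibble(do.call(rbind, vals))
}

#' @rdname read_points
#' @export
write_points <- function(points, path) {
  m <- as_point_matrix(points)
  rows <- apply(m, 1L, function(r) paste(sprintf("%.12g", r), collapse = " "))
  writeLines(rows, path)
  invisible(path)
}

#' Read and write ground-truth correspondence tables
#'
#' Tab-separated files with two integer columns (`scene`, `model`). On disk
#' the indices are 0-based (noted in the header comment); in R they are
#' 1-based.
#'
#' @param path File path.
#' @param truth Data frame with columns `scene`, `model`.
#' @export
read_truth <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) {
    return(tibble::tibble(scene = integer(0), model = integer(0)))
  }
  toks <- strsplit(trimws(lines), "\t| +")
  m <- do.call(rbind, lapply(toks, as.integer))
  tibble::tibble(scene = m[, 1L] + 1L, model = m[, 2L] + 1L)
}

#' @rdname read_truth
#' @export
write_truth <- function(truth, path) {
  writeLines(
    c("# scene_idx\tmodel_idx (0-based)",
      sprintf("%d\t%d", truth$scene - 1L, truth$model - 1L)),
    path
  )
  invisible(path)
}

#' Write or read a benchmark case as a directory
#'
#' The on-disk layout is `scene.txt` and `model.txt` (point files),
#' `truth.tsv` (0-based index pairs), and `spec.json`.
#'
#' @param case A `benchmark_case` from [make_benchmark_case()].
#' @param dir Directory path (created if missing).
#' @export
write_case <- function(case, dir) {
  stopifnot(inherits(case, "benchmark_case"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_points(case$scene, file.path(dir, "scene.txt"))
  write_points(case$model, file.path(dir, "model.txt"))
  write_truth(case$truth, file.path(dir, "truth.tsv"))
  jsonlite::write_json(case$spec, file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_case
#' @export
read_case <- function(dir) {
  spec <- jsonlite::read_json(file.path(dir, "spec.json"), simplifyVector = TRUE)
  base::structure(
    list(scene = read_points(file.path(dir, "scene.txt")),
         model = read_points(file.path(dir, "model.txt")),
         truth = read_truth(file.path(dir, "truth.tsv")),
         spec = spec),
    class = "benchmark_case"
  )
}

#' Serialize a fit as a replayable run report
#'
#' Writes a JSON report carrying the configuration echo, per-iteration traces
#' of (Q, sigma2, omega), final summary quantities, and timing, from which a
#' run can be reproduced (config + seed).
#'
#' @param fit A `cpd_fit`.
#' @param path Output JSON path.
#' @param seed Seed recorded for replay (if any randomness fed the inputs).
#' @param elapsed Elapsed seconds to record.
#' @param metrics Optional metrics tibble (e.g. from [evaluate_fit()]).
#' @export
write_run_report <- function(fit, path, seed = NULL, elapsed = NA_real_,
                             metrics = NULL) {
  stopifnot(inherits(fit, "cpd_fit"))
  report <- list(
    config = fit$config,
    seed = seed,
    n_iter = fit$n_iter,
    converged = fit$converged,
    sigma2 = fit$sigma2,
    omega = fit$omega,
    traces = as.list(fit$traces),
    elapsed_sec = elapsed
  )
  if (!is.null(metrics)) {
    report$metrics <- as.list(metrics[setdiff(names(metrics),
                                              "recall_accuracy")])
  }
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
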