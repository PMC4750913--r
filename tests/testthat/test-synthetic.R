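test_that("templates are deterministic, distinct and correctly sized", {
  r <- make_template("ring", 100)
  expect_equal(nrow(r), 100)
  expect_equal(sqrt(rowSums(as_point_matrix(r)^2)), rep(1, 100))
  expect_equal(nrow(unique(r)), 100)
  expect_identical(make_template("fishlike", 98, 1),
                   make_template("fishlike", 98, 1))
  expect_equal(nrow(make_template("fishlike", 98)), 98)
  expect_equal(nrow(make_template("glyph", 57)), 57)
  expect_error(make_template("ring", 10), class = "driftreg_invalid_input")
  expect_error(make_template("blob", 50), class = "driftreg_invalid_input")
})

test_that("templates are centred with unit RMS radius", {
  for (nm in c("ring", "fishlike", "glyph")) {
    m <- as_point_matrix(make_template(nm, 80))
    expect_lt(max(abs(colMeans(m))), 1e-10)
    expect_equal(sqrt(mean(rowSums(m^2))), 1, tolerance = 1e-10)
  }
})

test_that("deformation is smooth, seeded, anchored and scales with degree", {
  pts <- make_template("fishlike", 60)
  expect_equal(as_point_matrix(apply_deformation(pts, 0, seed = 1)),
               as_point_matrix(pts))
  expect_identical(apply_deformation(pts, 0.05, seed = 3)$x,
                   apply_deformation(pts, 0.05, seed = 3)$x)
  # mean displacement grows monotonically with degree (averaged over seeds)
  mean_disp <- function(degree) {
    mean(vapply(1:20, function(s) {
      w <- as_point_matrix(apply_deformation(pts, degree, seed = s))
      mean(sqrt(rowSums((w - as_point_matrix(pts))^2)))
    }, numeric(1)))
  }
  disp <- vapply(c(0.02, 0.05, 0.08), mean_disp, numeric(1))
  expect_true(all(diff(disp) > 0))
  # warping a translated set equals translating the warp
  shifted <- sweep(as_point_matrix(pts), 2, c(3, -4), "+")
  w0 <- as_point_matrix(apply_deformation(pts, 0.04, seed = 5))
  w1 <- as_point_matrix(apply_deformation(shifted, 0.04, seed = 5))
  expect_equal(w1, sweep(w0, 2, c(3, -4), "+"), tolerance = 1e-12)
})

test_that("noise jitter matches its nominal standard deviation", {
  pts <- make_template("ring", 25)
  expect_equal(as_point_matrix(add_noise(pts, 0, seed = 1)),
               as_point_matrix(pts))
  draws <- vapply(1:2000, function(s) {
    as_point_matrix(add_noise(pts, 0.05, seed = s)) - as_point_matrix(pts)
  }, matrix(0, 25, 2))
  expect_equal(sd(draws), 0.05, tolerance = 0.05 * 0.05)
  expect_false(identical(add_noise(pts, 0.05, seed = 1),
                         add_noise(pts, 0.05, seed = 2)))
})

test_that("occlusion removes one contiguous block in contour order", {
  pts <- make_template("ring", 100)
  occ <- apply_occlusion(pts, 0.5, seed = 4)
  expect_equal(nrow(occ), 50)
  expect_equal(attr(apply_occlusion(pts, 0, seed = 1), "kept"), 1:100)
  small <- make_template("ring", 20)
  for (s in 0:99) {
    kept <- attr(apply_occlusion(small, 0.4, seed = s), "kept")
    expect_equal(length(kept), 12)
    removed <- setdiff(1:20, kept)
    # the complement of one contiguous run (mod P) has exactly one gap > 1
    # in the circular difference sequence of the removed indices
    gaps <- diff(c(removed, removed[1] + 20))
    expect_equal(sum(gaps != 1), 1)
  }
  expect_error(apply_occlusion(small, 0.9, seed = 1),
               class = "driftreg_invalid_input")
})

test_that("outlier contamination appends uniform clutter inside the inflated box", {
  pts <- make_template("fishlike", 98)
  out <- add_outliers(pts, 1.0, seed = 6)
  expect_equal(nrow(out), 196)
  expect_equal(as_point_matrix(out)[1:98, ], as_point_matrix(pts))
  expect_equal(attr(out, "outlier_indices"), 99:196)
  expect_equal(nrow(add_outliers(make_template("ring", 100), 2.0, seed = 1)),
               300)
  expect_identical(add_outliers(pts, 0, seed = 3)$x, pts$x)
  m <- as_point_matrix(pts)
  lo <- apply(m, 2, min); hi <- apply(m, 2, max)
  mid <- (lo + hi) / 2; half <- (hi - lo) / 2 * 1.2
  clutter <- as_point_matrix(out)[99:196, ]
  expect_true(all(t(clutter) >= mid - half - 1e-12 &
                    t(clutter) <= mid + half + 1e-12))
})

test_that("benchmark cases compose counts, truth pairs and seeds correctly", {
  case <- make_benchmark_case("outlier", 1.0, template = "ring",
                              n_points = 98, seed = 3)
  expect_equal(nrow(case$scene), 196)
  expect_equal(nrow(case$truth), 98)
  occ <- make_benchmark_case("occlusion", 0.5, template = "ring",
                             n_points = 100, seed = 1)
  expect_equal(nrow(occ$truth), 50)
  expect_equal(nrow(occ$scene), 50)
  # identical spec -> identical case
  expect_identical(make_benchmark_case("noise", 0.03, seed = 7),
                   make_benchmark_case("noise", 0.03, seed = 7))
})

test_that("truth indices address the emitted arrays (coordinate round-trip)", {
  # with zero base deformation the scene rows are the model rows themselves
  occ <- make_benchmark_case("occlusion", 0.3, template = "glyph",
                             n_points = 60, seed = 5, base_deformation = 0)
  sc <- as_point_matrix(occ$scene)
  mo <- as_point_matrix(occ$model)
  expect_equal(sc[occ$truth$scene, ], mo[occ$truth$model, ], tolerance = 1e-12)
  out <- make_benchmark_case("outlier", 0.5, template = "ring",
                             n_points = 40, seed = 2, base_deformation = 0)
  expect_equal(as_point_matrix(out$scene)[out$truth$scene, ],
               as_point_matrix(out$model)[out$truth$model, ],
               tolerance = 1e-12)
})

test_that("undegraded cases register to near-zero error", {
  case <- make_benchmark_case("deformation", 0, template = "glyph",
                              n_points = 50, seed = 1)
  fit <- cpd_register(case$scene, case$model, omega0 = 0)
  expect_lt(rmse_points(fit$aligned, case$scene, case$truth), 1e-3)
})

test_that("benchmark initial outlier ratios follow the published grids", {
  expect_equal(default_omega0("deformation", 0.08), 0)
  expect_equal(default_omega0("noise", 0.03), 0.3)
  expect_equal(default_omega0("occlusion", 0.5), 0.5)
  expect_equal(default_omega0("outlier", 2.0), 0.7)
  expect_equal(default_omega0("outlier", 0.33), 0.5)  # off-grid fallback
})
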