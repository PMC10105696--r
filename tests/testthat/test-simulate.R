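test_that("templates honour the landmark protocol counts", {
  tpl <- make_template()
  expect_equal(nrow(tpl$points), 75L)
  expect_equal(sum(tpl$layout$role == "fixed"), 9L)
  small <- make_template(n_fixed = 4, n_semi = 4)
  expect_equal(nrow(small$points), 8L)
  expect_equal(small$allocation, rep(1L, 4))
  # deterministic given the seed
  expect_identical(make_template(seed = 7)$points,
                   make_template(seed = 7)$points)
  expect_false(identical(make_template(seed = 7)$points,
                         make_template(seed = 8)$points))
  # unit centroid size, closed non-degenerate outline
  expect_equal(centroid_size(tpl$points), 1, tolerance = 1e-9)
})

test_that("template semilandmarks are equidistant within each segment", {
  tpl <- make_template(seed = 3)
  semi <- tpl$layout[tpl$layout$role == "semi", ]
  for (s in unique(semi$segment)) {
    idx <- semi$point[semi$segment == s]
    pts <- tpl$points[idx, , drop = FALSE]
    gaps <- sqrt(rowSums(diff(pts)^2))
    # equal chordal gaps on the resampled polyline (loose: curvature varies)
    if (length(gaps) > 1) expect_lt(diff(range(gaps)) / mean(gaps), 0.1)
  }
})

test_that("zero effects and zero noise reproduce the template exactly", {
  design <- simulation_design(
    template = make_template(n_fixed = 6, n_semi = 6, seed = 2),
    groups = tibble::tibble(
      group = c("tarandus", "fennicus"),
      subspecies = c("tarandus", "fennicus"),
      status = c("wild_mountain", "wild_forest"),
      base_size = c(19, 21), shape_magnitude = c(0, 0)
    ),
    wear_classes = 1L, wear_magnitudes = 0, wear_size_factors = 1,
    sex_magnitude = 0, sex_size_factor = 1, noise_sd = 0, size_cv = 0,
    n_per_cell = 2L, seed = 5
  )
  sim <- simulate_dataset(design)
  arr <- coord_array(sim$dataset)
  for (i in seq_len(dim(arr)[3])) {
    expect_lt(procrustes_distance(arr[, , i], design$template$points), 1e-9)
  }
  # drawn sizes follow the group bases exactly when size_cv = 0
  cs <- apply(arr, 3, centroid_size)
  expect_setequal(round(unname(cs), 9), c(19, 21))
})

test_that("identical seeds give byte-identical TPS output", {
  d1 <- simulate_dataset(simulation_design(n_per_cell = 2L, seed = 11))
  d2 <- simulate_dataset(simulation_design(n_per_cell = 2L, seed = 11))
  f1 <- withr::local_tempfile(fileext = ".tps")
  f2 <- withr::local_tempfile(fileext = ".tps")
  write_tps(d1$dataset$landmarks, f1)
  write_tps(d2$dataset$landmarks, f2)
  expect_identical(readLines(f1), readLines(f2))
  d3 <- simulate_dataset(simulation_design(n_per_cell = 2L, seed = 12))
  expect_false(identical(d1$dataset$landmarks$x, d3$dataset$landmarks$x))
})

test_that("wear size factors order the mean centroid sizes", {
  design <- simulation_design(
    template = make_template(n_fixed = 6, n_semi = 12, seed = 4),
    wear_size_factors = c(1.00, 1.05, 1.10),
    n_per_cell = 25L, seed = 21
  )
  sim <- simulate_dataset(design)
  arr <- coord_array(sim$dataset)
  cs <- tibble::tibble(
    specimen_id = dimnames(arr)[[3]],
    size = apply(arr, 3, centroid_size)
  )
  cs <- dplyr::left_join(cs, sim$dataset$metadata, by = "specimen_id")
  means <- tapply(cs$size, cs$wear_class, mean)
  expect_true(all(diff(means) > 0))
})

test_that("planted effect ranking wear > subspecies > sex is recovered", {
  design <- simulation_design(
    template = make_template(n_fixed = 6, n_semi = 12, seed = 6),
    n_per_cell = 8L, seed = 31
  )
  sim <- simulate_dataset(design)
  al <- gpa(sim$dataset, tol = 1e-9)
  pct <- function(fac) {
    tab <- tidy(variance_decomposition(al, fac, n_perm = 49, seed = 1))
    tab$percent_variation[tab$term == fac]
  }
  p_wear <- pct("wear_class")
  p_sub <- pct("subspecies")
  p_sex <- pct("sex")
  expect_gt(p_wear, p_sub)
  expect_gt(p_sub, p_sex)
})

test_that("planted allometry is recovered when it dominates the noise", {
  design <- simulation_design(
    template = make_template(n_fixed = 6, n_semi = 12, seed = 8),
    groups = tibble::tibble(
      group = "tarandus", subspecies = "tarandus", status = "wild_mountain",
      base_size = 19, shape_magnitude = 0
    ),
    wear_classes = 1L, wear_magnitudes = 0, wear_size_factors = 1,
    sex_magnitude = 0, sex_size_factor = 1,
    allometry_magnitude = 0.2, noise_sd = 5e-4, size_cv = 0.15,
    n_per_cell = 25L, seed = 41
  )
  sim <- simulate_dataset(design)
  al <- gpa(sim$dataset, tol = 1e-9)
  res <- allometry_regression(al, n_perm = 99, seed = 2)
  expect_gt(res$r_squared, 0.9)
  expect_equal(res$p_value, 1 / 100)
})

test_that("invalid designs are rejected", {
  expect_error(simulation_design(wear_size_factors = c(1.1, 1.0, 1.0)),
               "non-decreasing")
  expect_error(simulation_design(noise_sd = -1), "non-negative")
  expect_error(simulation_design(n_per_cell = 0), "Empty")
})
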