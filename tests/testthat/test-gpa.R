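test_that("identical shapes under random similarity transforms superimpose exactly", {
  withr::local_seed(21)
  base <- toy_quad()
  shapes <- replicate(10, random_similarity(base), simplify = FALSE)
  al <- gpa(shapes, tol = 1e-12)
  n <- dim(al$shapes)[3]
  dmax <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dmax <- max(dmax, procrustes_distance(al$shapes[, , i],
                                            al$shapes[, , j]))
    }
  }
  expect_lt(dmax, 1e-8)
  expect_lt(procrustes_distance(al$consensus, base), 1e-8)
})

test_that("aligned shapes are centred with unit centroid size and mean consensus", {
  withr::local_seed(22)
  shapes <- replicate(6, random_similarity(toy_quad() +
                                             matrix(rnorm(8, sd = 0.1), 4, 2)),
                      simplify = FALSE)
  al <- gpa(shapes, tol = 1e-10)
  for (i in 1:6) {
    expect_lt(max(abs(colMeans(al$shapes[, , i]))), 1e-9)
    expect_lt(abs(sqrt(sum(al$shapes[, , i]^2)) - 1), 1e-9)
  }
  cons_hat <- apply(al$shapes, c(1, 2), mean)
  cons_hat <- cons_hat / sqrt(sum(cons_hat^2))
  expect_lt(max(abs(cons_hat - al$consensus)), 1e-9)
  expect_true(all(al$centroid_sizes > 0))
})

test_that("two-shape consensus matches a brute-force numerical minimiser", {
  a <- toy_quad()
  b <- matrix(c(0, 0.1, 2.1, 0, 2.2, 1.8, 0.1, 1.3), ncol = 2, byrow = TRUE)
  al <- gpa(list(a, b), tol = 1e-12)

  an <- scale(a, scale = FALSE); an <- an / sqrt(sum(an^2))
  bn <- scale(b, scale = FALSE); bn <- bn / sqrt(sum(bn^2))
  objective <- function(theta) {
    bt <- bn %*% rotation2(theta)
    cons <- (an + bt) / 2
    cons <- cons / sqrt(sum(cons^2))
    procrustes_distance(an, cons)^2 + procrustes_distance(bt, cons)^2
  }
  grid <- seq(-pi, pi, length.out = 2000)
  theta0 <- grid[which.min(vapply(grid, objective, numeric(1)))]
  opt <- stats::optimize(objective, c(theta0 - 0.01, theta0 + 0.01),
                         tol = 1e-12)
  bt <- bn %*% rotation2(opt$minimum)
  cons_oracle <- (an + bt) / 2
  cons_oracle <- cons_oracle / sqrt(sum(cons_oracle^2))
  expect_lt(procrustes_distance(al$consensus, cons_oracle), 1e-6)
  # and the achieved objective agrees
  total <- sum(vapply(1:2, function(i)
    procrustes_distance(al$shapes[, , i], al$consensus)^2, numeric(1)))
  expect_equal(total, opt$objective, tolerance = 1e-6)
})

test_that("GPA is invariant to specimen order and pre-applied transforms", {
  withr::local_seed(23)
  shapes <- replicate(8, toy_quad() + matrix(rnorm(8, sd = 0.08), 4, 2),
                      simplify = FALSE)
  al1 <- gpa(shapes, tol = 1e-12)
  al2 <- gpa(rev(shapes), tol = 1e-12)
  expect_lt(max(abs(al1$consensus - al2$consensus)), 1e-9)
  # same specimen, arbitrarily transformed, aligns to the same place
  shapes2 <- shapes
  shapes2[[3]] <- random_similarity(shapes2[[3]])
  al3 <- gpa(shapes2, tol = 1e-12)
  expect_lt(max(abs(al1$shapes[, , 3] - al3$shapes[, , 3])), 1e-8)
  expect_lt(max(abs(al1$consensus - al3$consensus)), 1e-9)
})

test_that("consensus minimises summed squared Procrustes distance", {
  withr::local_seed(24)
  shapes <- replicate(7, toy_quad() + matrix(rnorm(8, sd = 0.1), 4, 2),
                      simplify = FALSE)
  al <- gpa(shapes, tol = 1e-12)
  ssd <- function(ref) sum(vapply(1:7, function(i)
    procrustes_distance(al$shapes[, , i], ref)^2, numeric(1)))
  at_consensus <- ssd(al$consensus)
  for (rep in 1:10) {
    challenger <- al$consensus + matrix(rnorm(8, sd = 0.05), 4, 2)
    expect_lte(at_consensus, ssd(challenger) + 1e-12)
  }
})

test_that("GPA with sliding reaches a fixed point and reduces bending energy", {
  withr::local_seed(25)
  toy <- toy_outline()
  shapes <- replicate(6, random_similarity(
    toy$points + matrix(rnorm(16, sd = 0.03), 8, 2)
  ), simplify = FALSE)
  spec <- sliding_spec(toy$layout, max_outer_iterations = 10)
  plain <- gpa(shapes, tol = 1e-10)
  slid <- gpa(shapes, slide = spec, tol = 1e-10)
  be_plain <- bending_energy_model(plain$consensus)
  be_slid <- bending_energy_model(slid$consensus)
  e_plain <- mean(vapply(1:6, function(i)
    bending_energy(be_plain, plain$shapes[, , i]), numeric(1)))
  e_slid <- mean(vapply(1:6, function(i)
    bending_energy(be_slid, slid$shapes[, , i]), numeric(1)))
  expect_lt(e_slid, e_plain)
  # re-running the slid superimposition changes nothing (fixed point)
  again <- gpa(slid$shapes, slide = spec, tol = 1e-10)
  expect_lt(max(abs(again$consensus - slid$consensus)), 1e-5)
})

test_that("non-convergence warns and degenerate specimens are named", {
  withr::local_seed(26)
  shapes <- replicate(5, toy_quad() + matrix(rnorm(8, sd = 0.2), 4, 2),
                      simplify = FALSE)
  expect_warning(gpa(shapes, tol = 1e-16, max_iter = 1L), "did not converge")
  shapes[[2]] <- matrix(1, 4, 2)
  expect_error(gpa(shapes), "s02|specimen 2|Degenerate")
})
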