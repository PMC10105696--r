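test_that("two groups yield one canonical axis; identity covariance gives
           Euclidean Mahalanobis", {
  # within-group deviations constructed so pooled covariance is exactly I
  a <- sqrt(2)
  g1 <- rbind(c(a, 0), c(-a, 0), c(0, 0))
  g2 <- rbind(c(0, a), c(0, -a), c(0, 0))
  mu1 <- c(1, 2); mu2 <- c(4, 6)
  scores <- rbind(sweep(g1, 2, mu1, `+`), sweep(g2, 2, mu2, `+`))
  cv <- cva_fit(scores, rep(c("a", "b"), each = 3))
  expect_equal(ncol(cv$axes), 1L)
  expect_equal(cv$mahalanobis["a", "b"], sqrt(sum((mu1 - mu2)^2)),
               tolerance = 1e-9)
})

test_that("canonical axes match a dense generalized-eigen oracle", {
  withr::local_seed(71)
  n <- 30
  scores <- matrix(rnorm(n * 4), n, 4)
  groups <- rep(c("a", "b", "c"), each = 10)
  scores[groups == "b", 1] <- scores[groups == "b", 1] + 2
  scores[groups == "c", 2] <- scores[groups == "c", 2] + 3
  cv <- cva_fit(scores, groups)
  # oracle: eigenvectors of W^-1 B (non-symmetric dense solve)
  lv <- c("a", "b", "c")
  means <- rowsum(scores, groups) / 10
  ctr <- scores - means[match(groups, lv), ]
  w <- crossprod(ctr) / (n - 3)
  grand <- colMeans(scores)
  b <- crossprod(sweep(means, 2, grand) * sqrt(10)) / 2
  eo <- eigen(solve(w, b))
  for (j in 1:2) {
    u <- Re(eo$vectors[, j]); u <- u / sqrt(sum(u^2))
    v <- cv$axes[, j]; v <- v / sqrt(sum(v^2))
    expect_lt(min(max(abs(u - v)), max(abs(u + v))), 1e-7)
    expect_equal(cv$eigenvalues[j], Re(eo$values[j]), tolerance = 1e-7)
  }
  expect_error(cva_fit(scores, rep("a", n)), "at least 2 groups")
})

test_that("well-separated groups are classified perfectly; LOO equals a
           brute-force refit", {
  skip_if_not_installed("MASS")
  withr::local_seed(72)
  sim <- gaussian_two_group(10, p = 3, delta = 40)   # 20 sigma per side
  rep1 <- loo_cross_validate(sim$scores, sim$groups)
  expect_equal(glance(rep1)$overall, 100)

  # literal refit-per-held-out-specimen oracle via MASS::lda
  toy <- gaussian_two_group(6, p = 2, delta = 1.5)
  mine <- loo_cross_validate(toy$scores, toy$groups)
  oracle <- vapply(seq_len(12), function(i) {
    fit <- MASS::lda(toy$scores[-i, ], grouping = toy$groups[-i],
                     prior = c(0.5, 0.5))
    as.character(predict(fit, toy$scores[i, , drop = FALSE])$class)
  }, character(1))
  expect_equal(tidy(mine)$assigned, oracle)
  oracle_conf <- table(truth = toy$groups, assigned = oracle)
  expect_equal(unclass(mine$confusion), unclass(oracle_conf),
               ignore_attr = TRUE)
})

test_that("posteriors match direct Gaussian discriminant densities", {
  scores <- rbind(c(0, 0), c(0.4, 0.1), c(-0.2, -0.1),
                  c(3, 3), c(3.4, 2.9), c(2.8, 3.2))
  groups <- rep(c("a", "b"), each = 3)
  unknown <- rbind(c(0.5, 0.5), c(2, 2), c(1.45, 1.525))
  res <- classify_unknowns(scores, groups, unknown)
  # oracle: full Gaussian densities with the pooled covariance
  lv <- c("a", "b")
  means <- rowsum(scores, groups) / 3
  ctr <- scores - means[match(groups, lv), ]
  sw <- crossprod(ctr) / 4
  dens <- function(x, mu) {
    d <- x - mu
    exp(-0.5 * sum(d * solve(sw, d))) / (2 * pi * sqrt(det(sw)))
  }
  for (i in 1:3) {
    da <- dens(unknown[i, ], means[1, ]); db <- dens(unknown[i, ], means[2, ])
    expect_equal(unname(unlist(res$assignments[i, c("a", "b")])),
                 c(da, db) / (da + db), tolerance = 1e-9)
  }
  # at a group mean: assigned there with maximal posterior
  at_mean <- classify_unknowns(scores, groups, means["a", , drop = FALSE])
  expect_equal(at_mean$assignments$assigned, "a")
  # midpoint of the means: exact 0.5/0.5 by symmetry
  mid <- classify_unknowns(scores, groups,
                           rbind((means["a", ] + means["b", ]) / 2))
  expect_equal(mid$assignments$a, 0.5, tolerance = 1e-9)
  expect_true(mid$assignments$tie || abs(mid$assignments$a - 0.5) < 1e-9)
  expect_error(classify_unknowns(scores, groups, unknown[, 1, drop = FALSE]),
               "variables")
})

test_that("classification is invariant to joint affine transforms", {
  withr::local_seed(73)
  sim <- gaussian_two_group(15, p = 3, delta = 2)
  unknown <- matrix(rnorm(9), 3, 3)
  a <- matrix(rnorm(9), 3, 3) + diag(3)
  shift <- rnorm(3)
  t1 <- classify_unknowns(sim$scores, sim$groups, unknown)
  t2 <- classify_unknowns(sweep(sim$scores %*% a, 2, shift, `+`), sim$groups,
                          sweep(unknown %*% a, 2, shift, `+`))
  expect_equal(t1$assignments$a, t2$assignments$a, tolerance = 1e-7)
  l1 <- loo_cross_validate(sim$scores, sim$groups)
  l2 <- loo_cross_validate(sweep(sim$scores %*% a, 2, shift, `+`),
                           sim$groups)
  expect_equal(l1$confusion, l2$confusion)
})

test_that("randomly permuted labels classify at chance level", {
  withr::local_seed(74)
  x <- matrix(rnorm(100 * 3), 100, 3)
  g <- sample(rep(c("a", "b"), each = 50))
  acc <- glance(loo_cross_validate(x, g))$overall
  # central 99% binomial band around 50% for n = 100
  expect_gte(acc, 100 * qbinom(0.005, 100, 0.5) / 100)
  expect_lte(acc, 100 * qbinom(0.995, 100, 0.5) / 100)
})

test_that("unknown projection recovers training specimens and ignores pose", {
  withr::local_seed(75)
  toy <- toy_outline()
  shapes <- replicate(8, random_similarity(
    toy$points + matrix(rnorm(16, sd = 0.03), 8, 2)
  ), simplify = FALSE)
  spec <- sliding_spec(toy$layout, max_outer_iterations = 30,
                       tolerance = 1e-11)
  al <- gpa(shapes, slide = spec, tol = 1e-11)
  sp <- pca_shapes(al)

  # the consensus itself projects to the origin
  z <- project_unknowns(al, sp, array(al$consensus, c(8, 2, 1)))
  expect_lt(max(abs(z)), 1e-9)
  # a training specimen's raw configuration recovers its own scores
  arr <- simplify2array(shapes)
  z3 <- project_unknowns(al, sp, arr[, , 3, drop = FALSE])
  expect_lt(max(abs(z3 - sp$scores[3, ])), 1e-6)
  # pre-rotating an unknown changes nothing
  rot <- arr[, , 3] %*% rotation2(pi / 2)
  z3r <- project_unknowns(al, sp, array(rot, c(8, 2, 1)))
  expect_lt(max(abs(z3 - z3r)), 1e-9)
})

test_that("assignment summaries reproduce count/percent bookkeeping", {
  counts <- tibble::tibble(
    tooth = c("m1", "m1", "m2", "m2"),
    assigned = c("mountain", "forest", "mountain", "forest"),
    n = c(30, 6, 46, 8)
  )
  pooled <- summarize_assignments(counts)
  expect_equal(sum(pooled$n), 90)
  expect_equal(pooled$percent[pooled$assigned == "mountain"], 100 * 76 / 90)
  markkina <- summarize_assignments(
    tibble::tibble(assigned = c(rep("mountain", 19), rep("forest", 2)))
  )
  expect_equal(markkina$percent[markkina$assigned == "mountain"],
               100 * 19 / 21)
  single <- summarize_assignments(tibble::tibble(assigned = "forest"))
  expect_equal(single$percent, 100)
  expect_equal(single$percent_display, 100)
})
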