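test_that("perfect separation yields 100% explained and the minimal p", {
  y <- rbind(matrix(rep(c(0, 0, 1), 10), 10, 3, byrow = TRUE),
             matrix(rep(c(2, 1, 0), 10), 10, 3, byrow = TRUE))
  vd <- variance_decomposition(y, data.frame(g = rep(c("a", "b"), each = 10)),
                               n_perm = 199, seed = 4)
  tab <- tidy(vd)
  expect_equal(tab$percent_variation[tab$term == "g"], 100, tolerance = 1e-9)
  expect_equal(tab$p_value[tab$term == "g"], 1 / 200)
  expect_equal(sum(tab$percent_variation), 100, tolerance = 1e-6)
})

test_that("percent variation always totals 100 and p respects its floor", {
  withr::local_seed(41)
  y <- matrix(rnorm(60), 20, 3)
  f <- data.frame(a = rep(c("x", "y"), 10), b = rep(c("u", "v"), each = 10))
  vd <- variance_decomposition(y, f, n_perm = 99, seed = 2)
  tab <- tidy(vd)
  expect_equal(sum(tab$percent_variation), 100, tolerance = 1e-6)
  p <- tab$p_value[!is.na(tab$p_value)]
  expect_true(all(p >= 1 / 100 & p <= 1))
  expect_equal(nrow(tab), 4L)   # a, b, a:b, residual
})

test_that("sequential sums of squares and F match vegan::adonis2", {
  skip_if_not_installed("vegan")
  withr::local_seed(42)
  n <- 24
  y <- matrix(rnorm(n * 6), n, 6)
  f <- data.frame(a = sample(c("x", "y"), n, TRUE),
                  b = sample(c("u", "v", "w"), n, TRUE))
  vd <- variance_decomposition(y, f, n_perm = 99, seed = 9)
  tab <- tidy(vd)
  ad <- vegan::adonis2(dist(y) ~ a * b, data = f, permutations = 99,
                       by = "terms")
  expect_equal(tab$sum_sq, ad$SumOfSqs[1:4], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(tab$statistic[1:3], ad$F[1:3], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(tab$df, ad$Df[1:4], ignore_attr = TRUE)
})

test_that("explicit exhaustive permutations reproduce the enumerated p", {
  # n = 6, one factor: all 720 permutations enumerable
  y <- matrix(c(0.1, 0.4, 0.2, 1.3, 1.1, 1.6,
                0.0, 0.3, 0.1, 0.9, 1.2, 1.4), 6, 2)
  g <- rep(c("a", "b"), each = 3)
  perms <- as.matrix(expand.grid(rep(list(1:6), 6)))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 6), ]
  stopifnot(nrow(perms) == 720)

  # independent enumeration oracle: F statistic for every relabelling
  f_of <- function(yy, gg) {
    m <- rowsum(yy, gg) / 3
    grand <- colMeans(yy)
    ssb <- 3 * sum((sweep(m, 2, grand))^2)
    ssw <- sum((yy - m[match(gg, sort(unique(gg))), ])^2)
    (ssb / 1) / (ssw / 4)
  }
  f_obs <- f_of(y, g)
  f_perm <- apply(perms, 1, function(idx) f_of(y[idx, ], g))
  p_oracle <- sum(f_perm >= f_obs - 1e-12) / 720   # identity included

  # feed the 719 non-identity permutations: with the +1 for the observed
  # statistic this must equal the exhaustive enumeration exactly
  identity_row <- apply(perms, 1, function(r) all(r == 1:6))
  vd <- variance_decomposition(y, data.frame(g = g), seed = 1,
                               perms = perms[!identity_row, ])
  expect_equal(tidy(vd)$p_value[1], p_oracle)
})

test_that("the decomposition is invariant to specimen ordering", {
  withr::local_seed(43)
  y <- matrix(rnorm(36), 12, 3)
  f <- data.frame(g = rep(c("a", "b", "c"), each = 4))
  ord <- sample(12)
  v1 <- tidy(variance_decomposition(y, f, n_perm = 49, seed = 7))
  v2 <- tidy(variance_decomposition(y[ord, , drop = FALSE],
                                    data.frame(g = f$g[ord]),
                                    n_perm = 49, seed = 7))
  expect_equal(v1$sum_sq, v2$sum_sq, tolerance = 1e-9)
  expect_equal(v1$percent_variation, v2$percent_variation, tolerance = 1e-9)
})
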