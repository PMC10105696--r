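# Shared fixture builders. Everything is generated in code; no binary data.

rotation2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)
}

# Apply a random similarity transform (rotation, scale, translation).
random_similarity <- function(pts) {
  theta <- runif(1, 0, 2 * pi)
  s <- exp(runif(1, -0.5, 0.5))
  tr <- runif(2, -10, 10)
  sweep(s * pts %*% rotation2(theta), 2L, tr, `+`)
}

# An asymmetric 4-point shape (no reflection symmetry).
toy_quad <- function() {
  matrix(c(0, 0, 2, 0.2, 2.3, 1.5, 0.4, 1.1), ncol = 2, byrow = TRUE)
}

# A small open grid reference for TPS tests.
toy_grid <- function() {
  as.matrix(expand.grid(x = 0:2, y = 0:1))
}

# 8-point closed toy outline with 2 semilandmarks (points 2 and 6).
toy_outline <- function() {
  theta <- 2 * pi * (0:7) / 8
  pts <- cbind(cos(theta), sin(theta))
  layout <- tibble::tibble(
    point = 1:8,
    role = c("fixed", "semi", "fixed", "fixed", "fixed", "semi", "fixed",
             "fixed"),
    segment = c(NA, 1L, NA, NA, NA, 2L, NA, NA)
  )
  list(points = pts, layout = layout)
}

# Long-format coordinate tibble from a list of K x 2 matrices.
coords_from_list <- function(shapes, ids = NULL) {
  ids <- ids %||% sprintf("s%02d", seq_along(shapes))
  purrr::map_dfr(seq_along(shapes), function(i) {
    tibble::tibble(specimen_id = ids[[i]], point = seq_len(nrow(shapes[[i]])),
                   x = shapes[[i]][, 1], y = shapes[[i]][, 2])
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal valid metadata for a set of specimen ids.
stub_metadata <- function(ids, tooth = "m1", wear = 2L) {
  tibble::tibble(
    specimen_id = ids, tooth = tooth, wear_class = wear,
    subspecies = "tarandus", status = "domestic", sex = "F",
    population = "testpop", provenance = "modern"
  )
}

# Gaussian two-group score-space sample with true Mahalanobis separation
# `delta` between means (identity covariance, p dimensions).
gaussian_two_group <- function(n_per_group, p = 4L, delta = 2) {
  n <- 2L * n_per_group
  x <- matrix(rnorm(n * p), n, p)
  x[seq_len(n_per_group), 1] <- x[seq_len(n_per_group), 1] + delta / 2
  x[-seq_len(n_per_group), 1] <- x[-seq_len(n_per_group), 1] - delta / 2
  list(scores = x,
       groups = rep(c("a", "b"), each = n_per_group))
}
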