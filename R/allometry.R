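#' Allometry: multivariate regression of shape on log centroid size
#'
#' Regresses all tangent-space shape variables jointly on log-transformed
#' centroid size. The share of shape variance explained is
#' `R^2 = SS_model / SS_total` summed over shape variables; significance is
#' assessed by permuting the size values against the shapes.
#'
#' @param aligned An `mm_gpa` object with at least 4 specimens.
#' @param n_perm Number of permutations.
#' @param seed Permutation seed (recorded in the result).
#' @return An object of class `mm_allometry` with `r_squared`, `p_value`,
#'   `coefficients` (the 2K shape-per-log-size slope vector), `n_perm`,
#'   `seed`.
#' @export
allometry_regression <- function(aligned, n_perm = 999L, seed = 1L) {
  stopifnot(inherits(aligned, "mm_gpa"))
  y <- shape_matrix(aligned)
  if (nrow(y) < 4L) abort("Allometry regression needs at least 4 specimens")
  x <- log(aligned$centroid_sizes)
  if (sd(x) < 1e-12) abort("Centroid sizes are constant; allometry undefined")
  y <- sweep(y, 2L, colMeans(y))

  r2_of <- function(xv) {
    xc <- xv - mean(xv)
    beta <- crossprod(xc, y) / sum(xc^2)      # 1 x 2K slope
    sum((xc %*% beta)^2) / sum(y^2)
  }
  r2 <- r2_of(x)
  xc <- x - mean(x)
  slope <- as.vector(crossprod(xc, y) / sum(xc^2))

  rs <- init_rng(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    if (r2_of(sample(x)) >= r2 - 1e-15) exceed <- exceed + 1L
  }
  restore_rng(rs)

  structure(
    list(r_squared = r2, p_value = (1 + exceed) / (n_perm + 1),
         coefficients = slope, n_perm = n_perm, seed = seed,
         n = nrow(y)),
    class = "mm_allometry"
  )
}

#' @export
print.mm_allometry <- function(x, ...) {
  cat(sprintf(
    "<mm_allometry> R^2 = %.4f, permutation p = %.4g (%d permutations)\n",
    x$r_squared, x$p_value, x$n_perm
  ))
  invisible(x)
}

#' @describeIn allometry_regression One-row result table.
#' @param x An `mm_allometry` object.
#' @param ... Unused.
#' @export
tidy.mm_allometry <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, p_value = x$p_value,
                 n = x$n, n_permutations = x$n_perm, seed = x$seed)
}

#' @describeIn allometry_regression Alias of `tidy()` for this result.
#' @export
glance.mm_allometry <- function(x, ...) tidy(x)
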