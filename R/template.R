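#' Construct a molar-like outline template
#'
#' Builds a closed, non-self-intersecting, bilobed outline resembling the
#' enamel-dentine junction of a lower molar in occlusal view: a smooth
#' two-lobed curve `r(theta) = 1 + 0.3 cos(2 theta)` carrying `n_fixed`
#' fixed landmarks at deterministic positions (with a small seed-dependent
#' angular jitter so different seeds give slightly different templates) and
#' `n_semi` semilandmarks placed equidistantly along each inter-landmark
#' segment via [resample_equidistant()]. The default allocation splits the
#' semilandmarks as equally as possible across segments, remainder to the
#' longest segments by arc length. The template is centred and scaled to
#' unit centroid size.
#'
#' @param n_fixed Number of fixed landmarks (>= 3; default 9).
#' @param n_semi Number of semilandmarks (default 66).
#' @param seed Seed controlling the angular jitter; the template is fully
#'   deterministic given the seed.
#' @param allocation Optional per-segment semilandmark counts.
#' @return An object of class `mm_template`: `points` (K x 2, digitising
#'   order fixed-1, semis of segment 1, fixed-2, ...), `layout` (point-role
#'   tibble), `allocation`, `arc_lengths`.
#' @export
make_template <- function(n_fixed = 9L, n_semi = 66L, seed = 1L,
                          allocation = NULL) {
  stopifnot(n_fixed >= 3L, n_semi >= 0L)
  rs <- init_rng(seed)
  jitter <- runif(n_fixed, -0.03, 0.03)
  restore_rng(rs)
  theta_f <- sort(2 * pi * (seq_len(n_fixed) - 1) / n_fixed + jitter)
  outline <- function(theta) {
    r <- 1 + 0.3 * cos(2 * theta)
    cbind(r * cos(theta), r * sin(theta))
  }
  dense_arc <- function(a, b, n = 400L) {
    outline(seq(a, b, length.out = n))
  }
  # per-segment arc lengths (segment s runs from fixed s to fixed s+1, wrapping)
  theta_next <- c(theta_f[-1], theta_f[1] + 2 * pi)
  arcs <- vapply(seq_len(n_fixed), function(s) {
    p <- dense_arc(theta_f[s], theta_next[s])
    sum(sqrt(rowSums(diff(p)^2)))
  }, numeric(1))
  allocation <- allocation %||% semilandmark_allocation(n_fixed, n_semi, arcs)
  stopifnot(sum(allocation) == n_semi)

  pts <- list()
  for (s in seq_len(n_fixed)) {
    fixed_pt <- outline(theta_f[s])
    pts[[length(pts) + 1L]] <- fixed_pt
    if (allocation[s] > 0L) {
      seg <- dense_arc(theta_f[s], theta_next[s])
      res <- resample_equidistant(seg, allocation[s] + 2L)
      pts[[length(pts) + 1L]] <- res[-c(1L, nrow(res)), , drop = FALSE]
    }
  }
  points <- do.call(rbind, pts)
  points <- centre_points(points)
  points <- points / centroid_size(points)
  layout <- landmark_layout(n_fixed, n_semi, allocation)
  structure(
    list(points = points, layout = layout, allocation = allocation,
         arc_lengths = arcs),
    class = "mm_template"
  )
}

#' @export
print.mm_template <- function(x, ...) {
  cat(sprintf("<mm_template> %d points (%d fixed + %d semilandmarks)\n",
              nrow(x$points), sum(x$layout$role == "fixed"),
              sum(x$layout$role == "semi")))
  invisible(x)
}
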