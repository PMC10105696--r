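#' Specification of the semilandmark sliding step
#'
#' @param layout Point-role layout tibble from [landmark_layout()].
#' @param max_outer_iterations Maximum number of outer GPA + sliding cycles.
#' @param tolerance Convergence tolerance on the mean consensus displacement.
#' @param tangent_mode `"chord"` (default): the sliding tangent at a
#'   semilandmark is the chord through its two outline neighbours, and slid
#'   points stay on that tangent line (pure linearised sliding).
#'   `"projected_curve"`: after sliding, each semilandmark is re-projected
#'   onto the piecewise-linear outline of the original configuration.
#' @param closed Whether the outline is a closed curve (neighbours wrap).
#' @return A `sliding_spec` list.
#' @export
sliding_spec <- function(layout,
                         max_outer_iterations = 5L,
                         tolerance = 1e-6,
                         tangent_mode = c("chord", "projected_curve"),
                         closed = TRUE) {
  tangent_mode <- match.arg(tangent_mode)
  stopifnot(tolerance > 0, max_outer_iterations >= 1L)
  structure(
    list(layout = layout, max_outer_iterations = as.integer(max_outer_iterations),
         tolerance = tolerance, tangent_mode = tangent_mode, closed = closed),
    class = "sliding_spec"
  )
}

# Unit tangent directions at every semilandmark: chord through the two
# neighbouring points along the outline (previous and next in digitising
# order, wrapping when the outline is closed; at an open end the point's
# own neighbour pair degenerates to the adjacent chord).
semilandmark_tangents <- function(pts, semi_idx, closed = TRUE) {
  k <- nrow(pts)
  prev <- semi_idx - 1L
  nxt <- semi_idx + 1L
  if (closed) {
    prev[prev < 1L] <- k
    nxt[nxt > k] <- 1L
  } else {
    prev[prev < 1L] <- 1L
    nxt[nxt > k] <- k
  }
  tang <- pts[nxt, , drop = FALSE] - pts[prev, , drop = FALSE]
  len <- sqrt(rowSums(tang^2))
  zero <- which(len < 1e-12)
  if (length(zero) > 0L) {
    abort(paste0("Zero-length sliding tangent at point(s) ",
                 paste(semi_idx[zero], collapse = ", "),
                 " (coincident neighbours)"))
  }
  tang / len
}

#' Slide semilandmarks to minimise thin-plate spline bending energy
#'
#' Semilandmarks lack point-wise homology along the outline; during
#' superimposition they are allowed to slide along their local tangent
#' direction so that the thin-plate spline deformation from the reference to
#' the configuration is as smooth as possible. All sliding amplitudes are
#' solved jointly from one linear system (the exact minimiser of the
#' quadratic bending energy restricted to tangential displacements), so the
#' energy after sliding can never exceed the energy before. Fixed landmarks
#' never move. The configuration is assumed to be already superimposed on
#' the reference (same position, scale and orientation).
#'
#' @param config K x 2 matrix (or `x`/`y` tibble) of the configuration.
#' @param reference K x 2 matrix, or a precomputed [bending_energy_model()].
#' @param spec A [sliding_spec()] describing roles and tangent handling.
#' @param tangents Optional precomputed unit tangents (one row per
#'   semilandmark). By default tangents are chords through each
#'   semilandmark's outline neighbours on the configuration itself; inside
#'   [gpa()] they are evaluated on the consensus instead, which makes the
#'   slide step a fixed projection (idempotent, drift-free) shared by all
#'   specimens.
#' @return K x 2 matrix with slid semilandmark positions.
#' @export
slide_semilandmarks <- function(config, reference, spec, tangents = NULL) {
  stopifnot(inherits(spec, "sliding_spec"))
  pts <- as_points_matrix(config)
  model <- if (inherits(reference, "bending_energy")) reference else {
    bending_energy_model(reference)
  }
  if (nrow(pts) != nrow(model$reference)) {
    abort("Configuration and reference must share K")
  }
  semi_idx <- spec$layout$point[spec$layout$role == "semi"]
  if (length(semi_idx) == 0L) return(pts)

  b <- model$energy_matrix
  tang <- tangents %||% semilandmark_tangents(pts, semi_idx, spec$closed)
  stopifnot(nrow(tang) == length(semi_idx))
  d <- pts - model$reference
  m <- length(semi_idx)
  # T_x, T_y: K x m, column j moves point semi_idx[j] along tang[j, ]
  tx <- matrix(0, nrow(pts), m); ty <- matrix(0, nrow(pts), m)
  tx[cbind(semi_idx, seq_len(m))] <- tang[, 1]
  ty[cbind(semi_idx, seq_len(m))] <- tang[, 2]
  btx <- b %*% tx; bty <- b %*% ty
  a <- crossprod(tx, btx) + crossprod(ty, bty)
  rhs <- -(crossprod(tx, b %*% d[, 1]) + crossprod(ty, b %*% d[, 2]))
  t_amp <- tryCatch(solve(a, rhs), error = function(e) {
    ridge <- diag(1e-12 * max(diag(a)), m)
    solve(a + ridge, rhs)
  })
  out <- pts
  out[semi_idx, 1] <- out[semi_idx, 1] + t_amp * tang[, 1]
  out[semi_idx, 2] <- out[semi_idx, 2] + t_amp * tang[, 2]
  if (spec$tangent_mode == "projected_curve") {
    out[semi_idx, ] <- project_onto_polyline(out[semi_idx, , drop = FALSE],
                                             pts, spec$closed)
  }
  out
}

# Nearest point on a (possibly closed) polyline for each query point.
project_onto_polyline <- function(query, poly, closed = TRUE) {
  verts <- if (closed) rbind(poly, poly[1L, , drop = FALSE]) else poly
  seg_a <- verts[-nrow(verts), , drop = FALSE]
  seg_d <- diff(verts)
  seg_l2 <- rowSums(seg_d^2)
  out <- query
  for (i in seq_len(nrow(query))) {
    q <- query[i, ]
    tpar <- (sweep(seg_a, 2L, q, `-`) * -seg_d)
    tpar <- rowSums(tpar) / pmax(seg_l2, 1e-300)
    tpar <- pmin(pmax(tpar, 0), 1)
    cand <- seg_a + seg_d * tpar
    d2 <- rowSums(sweep(cand, 2L, q)^2)
    out[i, ] <- cand[which.min(d2), ]
  }
  out
}
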