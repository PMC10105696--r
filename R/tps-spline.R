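#' Bending-energy matrix of a thin-plate spline reference
#'
#' For a 2D reference configuration the thin-plate spline interpolant between
#' the reference and any target decomposes into an affine part and a bent
#' part; the bending energy is a quadratic form `d' B d` in the target
#' displacements `d`, applied to the x and y displacement vectors separately.
#' `B` is the upper-left K x K block of the inverse of the bordered kernel
#' system `L = [[U, P], [P', 0]]` with kernel `U(r) = r^2 log(r^2)` and
#' `P = [1, x, y]`. `B` is symmetric positive semi-definite and annihilates
#' every affine displacement field.
#'
#' @param reference K x 2 matrix (K >= 4, no coincident points).
#' @return An object of class `bending_energy` with elements `reference`
#'   and `energy_matrix` (K x K).
#' @export
bending_energy_model <- function(reference) {
  ref <- as_points_matrix(reference)
  k <- nrow(ref)
  if (k < 4L) abort("Bending energy needs at least 4 reference points")
  d2 <- as.matrix(stats::dist(ref))^2
  if (any(d2[upper.tri(d2)] < 1e-24)) {
    abort("Coincident points in reference: TPS kernel is singular")
  }
  u <- ifelse(d2 > 0, d2 * log(d2), 0)
  p <- cbind(1, ref)
  l <- rbind(cbind(u, p), cbind(t(p), matrix(0, 3L, 3L)))
  l_inv <- tryCatch(solve(l), error = function(e) {
    abort("Singular TPS system for this reference (degenerate geometry)")
  })
  b <- l_inv[seq_len(k), seq_len(k), drop = FALSE]
  b <- (b + t(b)) / 2
  structure(list(reference = ref, energy_matrix = b),
            class = "bending_energy")
}

#' Bending energy of a target configuration relative to a reference
#'
#' @param model A `bending_energy` object from [bending_energy_model()].
#' @param target K x 2 matrix with the same K as the reference.
#' @return Non-negative scalar; zero exactly when the target is an affine
#'   transform of the reference.
#' @export
bending_energy <- function(model, target) {
  stopifnot(inherits(model, "bending_energy"))
  tgt <- as_points_matrix(target)
  if (nrow(tgt) != nrow(model$reference)) {
    abort("Target and reference must have the same number of points")
  }
  d <- tgt - model$reference
  e <- sum(d[, 1] * (model$energy_matrix %*% d[, 1])) +
    sum(d[, 2] * (model$energy_matrix %*% d[, 2]))
  max(0, e)
}

#' Thin-plate spline interpolation coefficients (direct solve)
#'
#' Solves the full TPS interpolation system mapping the reference onto the
#' target and returns the coefficients together with the bending energy
#' computed from them. Primarily a verification path for
#' [bending_energy()]; both use `U(r) = r^2 log(r^2)`.
#'
#' @inheritParams bending_energy
#' @return List with `weights` (K x 2 non-affine coefficients), `affine`
#'   (3 x 2), and `energy`.
#' @export
tps_solve <- function(model, target) {
  stopifnot(inherits(model, "bending_energy"))
  ref <- model$reference
  tgt <- as_points_matrix(target)
  k <- nrow(ref)
  d2 <- as.matrix(stats::dist(ref))^2
  u <- ifelse(d2 > 0, d2 * log(d2), 0)
  p <- cbind(1, ref)
  l <- rbind(cbind(u, p), cbind(t(p), matrix(0, 3L, 3L)))
  rhs <- rbind(tgt, matrix(0, 3L, 2L))
  coefs <- solve(l, rhs)
  w <- coefs[seq_len(k), , drop = FALSE]
  energy <- sum(w[, 1] * (u %*% w[, 1])) + sum(w[, 2] * (u %*% w[, 2]))
  list(weights = w, affine = coefs[k + 1:3, , drop = FALSE],
       energy = max(0, energy))
}
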