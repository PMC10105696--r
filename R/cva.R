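#' Canonical variate analysis on retained component scores
#'
#' Solves the between-group / pooled-within-group generalized eigenproblem
#' on a (typically PCA-reduced) score matrix, yielding at most `g - 1`
#' canonical axes and the Mahalanobis distances between group means under
#' the pooled within-group covariance.
#'
#' If the number of variables reaches the sample size minus the number of
#' groups, the trailing variables are dropped with a warning (the input is
#' assumed ordered by decreasing variance, as PCA scores are); if the pooled
#' covariance is ill-conditioned (condition number above 1e10) it is shrunk
#' toward its diagonal with weight 1e-8, with a warning.
#'
#' @param scores n x p numeric matrix (rows = specimens).
#' @param groups Group labels of length n; at least 2 groups with at least
#'   2 members each.
#' @return An object of class `mm_cva` with `labels`, `sizes`, `axes`
#'   (p x n_axes, unit Mahalanobis norm), `eigenvalues`, `group_means`
#'   (original space), `canonical_means`, `pooled_cov`, `mahalanobis`
#'   (g x g symmetric), `n_variables` (after any auto-reduction).
#' @export
cva_fit <- function(scores, groups) {
  scores <- as.matrix(scores)
  groups <- as.character(groups)
  stopifnot(nrow(scores) == length(groups))
  lv <- sort(unique(groups))
  g <- length(lv)
  if (g < 2L) abort("CVA needs at least 2 groups")
  sizes <- table(factor(groups, levels = lv))
  if (any(sizes < 2L)) {
    abort(paste0("Group(s) with fewer than 2 members: ",
                 paste(lv[sizes < 2L], collapse = ", ")))
  }
  n <- nrow(scores)
  p_max <- n - g
  if (ncol(scores) > p_max) {
    warn(sprintf(
      "Reducing %d variables to %d (sample size minus groups) before CVA",
      ncol(scores), p_max
    ))
    scores <- scores[, seq_len(p_max), drop = FALSE]
  }
  p <- ncol(scores)

  means <- rowsum(scores, groups) / as.vector(sizes)
  centred <- scores - means[match(groups, lv), , drop = FALSE]
  sw <- crossprod(centred) / (n - g)
  ev_w <- eigen(sw, symmetric = TRUE)
  cond <- ev_w$values[1] / max(ev_w$values[p], .Machine$double.xmin)
  if (!is.finite(cond) || cond > 1e10) {
    warn("Ill-conditioned pooled covariance; shrinking toward its diagonal")
    sw <- (1 - 1e-8) * sw + 1e-8 * diag(diag(sw), p)
    ev_w <- eigen(sw, symmetric = TRUE)
  }
  w_inv_half <- ev_w$vectors %*% diag(1 / sqrt(pmax(ev_w$values, 1e-300)), p) %*%
    t(ev_w$vectors)
  grand <- colMeans(scores)
  md <- sweep(means, 2L, grand)
  b <- crossprod(md * sqrt(as.vector(sizes))) / (g - 1)
  m <- w_inv_half %*% b %*% w_inv_half
  ev_b <- eigen((m + t(m)) / 2, symmetric = TRUE)
  n_axes <- min(g - 1L, p)
  axes <- w_inv_half %*% ev_b$vectors[, seq_len(n_axes), drop = FALSE]
  flip <- apply(axes, 2L, function(v) if (v[which.max(abs(v))] < 0) -1 else 1)
  axes <- sweep(axes, 2L, flip, `*`)
  colnames(axes) <- paste0("CV", seq_len(n_axes))

  sw_inv <- w_inv_half %*% w_inv_half
  maha <- matrix(0, g, g, dimnames = list(lv, lv))
  for (i in seq_len(g - 1L)) {
    for (j in (i + 1L):g) {
      d <- means[i, ] - means[j, ]
      maha[i, j] <- maha[j, i] <- sqrt(max(0, sum(d * (sw_inv %*% d))))
    }
  }

  structure(
    list(labels = lv, sizes = as.vector(sizes), axes = axes,
         eigenvalues = ev_b$values[seq_len(n_axes)],
         group_means = means, canonical_means = means %*% axes,
         pooled_cov = sw, pooled_cov_inv = sw_inv,
         mahalanobis = maha, n_variables = p, grand_mean = grand),
    class = "mm_cva"
  )
}

#' @export
print.mm_cva <- function(x, ...) {
  cat(sprintf("<mm_cva> %d groups (%s), %d canonical axes on %d variables\n",
              length(x$labels), paste(x$labels, collapse = ", "),
              ncol(x$axes), x$n_variables))
  cat("Mahalanobis distances:\n")
  print(round(x$mahalanobis, 3))
  invisible(x)
}

#' @describeIn cva_fit Pairwise Mahalanobis distances in long format.
#' @param x An `mm_cva` object.
#' @param ... Unused.
#' @export
tidy.mm_cva <- function(x, ...) {
  g <- length(x$labels)
  idx <- which(upper.tri(x$mahalanobis), arr.ind = TRUE)
  tibble::tibble(
    group1 = x$labels[idx[, 1]], group2 = x$labels[idx[, 2]],
    mahalanobis = x$mahalanobis[idx]
  )
}

#' @describeIn cva_fit One-row summary.
#' @export
glance.mm_cva <- function(x, ...) {
  tibble::tibble(n_groups = length(x$labels), n_axes = ncol(x$axes),
                 n_variables = x$n_variables,
                 eigenvalue_1 = x$eigenvalues[1])
}

#' @describeIn cva_fit Group means in canonical space (first two axes).
#' @param object An `mm_cva` object.
#' @export
autoplot.mm_cva <- function(object, ...) {
  cm <- object$canonical_means
  df <- tibble::tibble(
    group = object$labels, CV1 = cm[, 1],
    CV2 = if (ncol(cm) > 1) cm[, 2] else 0
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$CV1, y = .data$CV2,
                                   label = .data$group)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.8) +
    ggplot2::labs(title = "Canonical variate group means")
}
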