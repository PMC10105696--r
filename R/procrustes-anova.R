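#' Procrustes ANOVA: permutation variance decomposition of shape
#'
#' Decomposes the total variance of the Procrustes-aligned shape coordinates
#' into sequential (Type I) sums of squares for one or two factors, the
#' interaction last, and reports the percentage of shape variation explained
#' by each term. This Goodall-style sum-of-squares decomposition is what a
#' "% of shape variation explained by wear/tooth" statement quantifies;
#' significance is assessed by permutation of reduced-model residuals
#' (Freedman-Lane), so each term's null distribution conditions on all
#' previously entered terms.
#'
#' @param aligned An `mm_gpa` object whose `metadata` holds the factors, or
#'   any object accepted by [shape_matrix()].
#' @param factors Character vector of one or two metadata column names
#'   (order matters: sequential SS), or a data frame of factor columns.
#' @param n_perm Number of random permutations (>= 99 recommended; fewer
#'   raises a warning).
#' @param seed Seed for the permutation draws (mandatory; recorded in the
#'   result).
#' @param interaction Include the interaction term for two factors
#'   (default `TRUE`).
#' @param perms Optional integer matrix of explicit permutations (one per
#'   row) to use instead of random draws, e.g. for exhaustive enumeration
#'   on small samples.
#' @return An object of class `mm_variance_decomposition`; `tidy()` returns
#'   the term table (term, df, sum of squares, percent variation, F,
#'   permutation p) including the residual row.
#' @export
variance_decomposition <- function(aligned, factors, n_perm = 999L,
                                   seed = 1L, interaction = TRUE,
                                   perms = NULL) {
  if (inherits(aligned, "mm_gpa")) {
    y <- shape_matrix(aligned)
    fac_df <- if (is.data.frame(factors)) factors else {
      if (is.null(aligned$metadata)) abort("No metadata attached to this GPA")
      aligned$metadata[, factors, drop = FALSE]
    }
  } else {
    y <- as.matrix(aligned)
    fac_df <- as.data.frame(factors, stringsAsFactors = FALSE)
  }
  fac_df <- as.data.frame(lapply(fac_df, factor))
  if (ncol(fac_df) < 1L || ncol(fac_df) > 2L) {
    abort("variance_decomposition takes one or two factors")
  }
  for (nm in names(fac_df)) {
    if (nlevels(fac_df[[nm]]) < 2L) {
      abort(sprintf("Factor '%s' has fewer than 2 levels", nm))
    }
  }
  if (is.null(perms) && n_perm < 99L) {
    warn("n_perm < 99 gives a coarse permutation p-value")
  }
  n <- nrow(y)
  y <- sweep(y, 2L, colMeans(y))
  ss_total <- sum(y^2)

  two <- ncol(fac_df) == 2L && interaction
  term_names <- names(fac_df)
  formulas <- list()
  if (ncol(fac_df) == 1L) {
    formulas[[term_names[1]]] <- ~f1
  } else {
    formulas[[term_names[1]]] <- ~f1
    formulas[[term_names[2]]] <- ~f1 + f2
    if (two) formulas[[paste(term_names, collapse = ":")]] <- ~f1 * f2
  }
  dat <- data.frame(f1 = fac_df[[1]])
  if (ncol(fac_df) == 2L) dat$f2 <- fac_df[[2]]

  # Hat-matrix Q factors for the cumulative models
  qrs <- lapply(formulas, function(f) qr(model.matrix(f, dat)))
  fit_ss <- function(yy) {
    # Fitted sums of squares under each cumulative model
    vapply(qrs, function(q) {
      f <- qr.fitted(q, yy)
      sum(f^2) - n * sum(colMeans(yy)^2)
    }, numeric(1))
  }
  cum_ss <- fit_ss(y)
  term_ss <- diff(c(0, cum_ss))
  ranks <- vapply(qrs, `[[`, integer(1), "rank")
  term_df <- diff(c(1L, ranks))
  ss_res <- ss_total - sum(term_ss)
  df_res <- n - ranks[[length(ranks)]]
  if (df_res <= 0L) abort("No residual degrees of freedom")
  ms_res <- ss_res / df_res
  f_stat <- (term_ss / term_df) / ms_res

  n_terms <- length(term_ss)
  if (is.null(perms)) {
    rs <- init_rng(seed)
    perms <- t(vapply(seq_len(n_perm), function(i) sample.int(n),
                      integer(n)))
    restore_rng(rs)
  } else {
    perms <- as.matrix(perms)
    stopifnot(ncol(perms) == n)
    n_perm <- nrow(perms)
  }
  exceed <- numeric(n_terms)
  # Freedman-Lane: permute residuals of the reduced (previous) model
  for (k in seq_len(n_terms)) {
    if (k == 1L) {
      red_fit <- matrix(0, n, ncol(y))  # intercept only: y is centred
      red_res <- y
    } else {
      red_fit <- qr.fitted(qrs[[k - 1L]], y)
      red_res <- y - red_fit
    }
    for (b in seq_len(n_perm)) {
      y_star <- red_fit + red_res[perms[b, ], , drop = FALSE]
      y_star <- sweep(y_star, 2L, colMeans(y_star))
      cum_star <- fit_ss(y_star)
      ts <- diff(c(0, cum_star))
      res_star <- sum(y_star^2) - sum(ts)
      f_star <- (ts[[k]] / term_df[[k]]) / (res_star / df_res)
      threshold <- if (is.finite(f_stat[[k]])) {
        f_stat[[k]] - 1e-12 * abs(f_stat[[k]])
      } else {
        f_stat[[k]]   # infinite observed F: only an infinite F* matches
      }
      if (isTRUE(f_star >= threshold)) exceed[[k]] <- exceed[[k]] + 1
    }
  }
  p_vals <- (1 + exceed) / (n_perm + 1)

  tab <- tibble::tibble(
    term = c(names(formulas), "residual"),
    df = unname(c(term_df, df_res)),
    sum_sq = unname(c(term_ss, ss_res)),
    percent_variation = unname(100 * c(term_ss, ss_res) / ss_total),
    statistic = unname(c(f_stat, NA_real_)),
    p_value = unname(c(p_vals, NA_real_))
  )
  structure(
    list(terms = tab, ss_total = ss_total, n_permutations = n_perm,
         seed = seed),
    class = "mm_variance_decomposition"
  )
}

#' @export
print.mm_variance_decomposition <- function(x, ...) {
  cat(sprintf("<mm_variance_decomposition> %d permutations, seed %s\n",
              x$n_permutations, format(x$seed)))
  print(x$terms)
  invisible(x)
}

#' @describeIn variance_decomposition Term table as a tibble.
#' @param x An `mm_variance_decomposition` object.
#' @param ... Unused.
#' @export
tidy.mm_variance_decomposition <- function(x, ...) x$terms

#' @describeIn variance_decomposition One-row summary.
#' @export
glance.mm_variance_decomposition <- function(x, ...) {
  tibble::tibble(ss_total = x$ss_total,
                 n_permutations = x$n_permutations, seed = x$seed)
}

#' Parametric MANOVA on retained principal component scores
#'
#' Secondary route to group differences in shape: a classical MANOVA
#' (Wilks' lambda) on the principal component scores retaining a given
#' share of total variance. Complements [variance_decomposition()], which
#' reports a sum-of-squares decomposition instead of a Wilks statistic.
#'
#' @param space An `mm_pca` with metadata.
#' @param factors One or two metadata column names.
#' @param threshold Variance retention passed to [retain_components()].
#' @return The term table of `summary(manova(...), test = "Wilks")` as a
#'   tibble.
#' @export
manova_scores <- function(space, factors, threshold = 0.95) {
  stopifnot(inherits(space, "mm_pca"))
  kept <- retain_components(space, threshold)
  dat <- as.data.frame(lapply(space$metadata[, factors, drop = FALSE], factor))
  names(dat) <- paste0("f", seq_along(factors))
  rhs <- paste(names(dat), collapse = " * ")
  fit <- stats::manova(stats::as.formula(paste("kept$scores ~", rhs)),
                       data = dat)
  sm <- summary(fit, test = "Wilks")$stats
  out <- tibble::as_tibble(sm, rownames = "term")
  names(out) <- c("term", "df", "wilks", "approx_f", "num_df", "den_df",
                  "p_value")
  out$term <- sub("^f1$", factors[1], out$term)
  if (length(factors) > 1) out$term <- sub("^f2$", factors[2], out$term)
  out
}
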