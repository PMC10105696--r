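#' Size comparison tests on log centroid size
#'
#' Centroid sizes are log-transformed, compared across groups with a one-way
#' ANOVA (the overall test at the conventional 5% error threshold), and then
#' pairwise with Wilcoxon rank-sum tests. The exact Wilcoxon null
#' distribution is used when both groups have at most 25 members and no
#' ties; otherwise the normal approximation with continuity correction on
#' mid-ranks is used. All pairwise p-values are corrected for the false
#' discovery rate by the Benjamini-Hochberg step-up procedure.
#'
#' @param sizes Positive numeric vector of centroid sizes, or an `mm_gpa`
#'   object (its stored sizes are used).
#' @param groups Group labels, same length as `sizes`, or (for an `mm_gpa`
#'   input) the name of a metadata column.
#' @param log_transform Log-transform sizes first (default `TRUE`).
#' @return An object of class `mm_size_tests` with the ANOVA table, the
#'   pairwise table (`tidy()`), and symmetric raw/adjusted p-value matrices.
#'   Groups with fewer than 2 members are excluded with a warning.
#' @export
size_tests <- function(sizes, groups, log_transform = TRUE) {
  if (inherits(sizes, "mm_gpa")) {
    gpa_obj <- sizes
    sizes <- gpa_obj$centroid_sizes
    if (is.character(groups) && length(groups) == 1L) {
      groups <- gpa_obj$metadata[[groups]]
    }
  }
  stopifnot(length(sizes) == length(groups))
  groups <- as.character(groups)
  tab <- table(groups)
  small <- names(tab)[tab < 2L]
  if (length(small) > 0L) {
    warn(paste0("Excluding group(s) with fewer than 2 members: ",
                paste(small, collapse = ", ")))
    keep <- !(groups %in% small)
    sizes <- sizes[keep]; groups <- groups[keep]
  }
  lv <- sort(unique(groups))
  if (length(lv) < 2L) abort("size_tests needs at least 2 groups of size >= 2")
  y <- if (log_transform) log(sizes) else sizes

  fit <- aov(y ~ g, data = data.frame(y = y, g = factor(groups, levels = lv)))
  an <- summary(fit)[[1]]
  anova_tab <- tibble::tibble(
    term = c("group", "residual"),
    df = an[["Df"]], sum_sq = an[["Sum Sq"]],
    statistic = an[["F value"]], p_value = an[["Pr(>F)"]]
  )

  pairs <- utils::combn(lv, 2L)
  pw <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    y1 <- y[groups == g1]; y2 <- y[groups == g2]
    ties <- anyDuplicated(c(y1, y2)) > 0L
    exact <- length(y1) <= 25L && length(y2) <= 25L && !ties
    wt <- suppressWarnings(
      wilcox.test(y1, y2, exact = exact, correct = TRUE)
    )
    tibble::tibble(group1 = g1, group2 = g2, n1 = length(y1),
                   n2 = length(y2), statistic = unname(wt$statistic),
                   p_value = wt$p.value, exact = exact)
  })
  pw$p_adjusted <- p.adjust(pw$p_value, method = "BH")

  pmat <- matrix(NA_real_, length(lv), length(lv), dimnames = list(lv, lv))
  amat <- pmat
  diag(pmat) <- diag(amat) <- 1
  for (j in seq_len(nrow(pw))) {
    pmat[pw$group1[j], pw$group2[j]] <- pmat[pw$group2[j], pw$group1[j]] <-
      pw$p_value[j]
    amat[pw$group1[j], pw$group2[j]] <- amat[pw$group2[j], pw$group1[j]] <-
      pw$p_adjusted[j]
  }
  structure(
    list(anova = anova_tab, pairwise = pw, p_matrix = pmat,
         p_adjusted_matrix = amat, log_transform = log_transform),
    class = "mm_size_tests"
  )
}

#' @export
print.mm_size_tests <- function(x, ...) {
  cat("<mm_size_tests>\n  ANOVA",
      if (x$log_transform) "on log centroid size:\n" else ":\n")
  print(x$anova)
  cat("  Pairwise Wilcoxon (BH-adjusted):\n")
  print(x$pairwise)
  invisible(x)
}

#' @describeIn size_tests Pairwise Wilcoxon table with BH-adjusted
#'   p-values.
#' @param x An `mm_size_tests` object.
#' @param ... Unused.
#' @export
tidy.mm_size_tests <- function(x, ...) x$pairwise

#' @describeIn size_tests The overall ANOVA row.
#' @export
glance.mm_size_tests <- function(x, ...) {
  tibble::tibble(
    f_statistic = x$anova$statistic[1],
    df = x$anova$df[1], df_residual = x$anova$df[2],
    p_value = x$anova$p_value[1],
    n_pairs = nrow(x$pairwise)
  )
}
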