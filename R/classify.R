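# Gaussian linear discriminant with pooled covariance: the classifier used
# both for leave-one-out cross-validation and for assigning archaeological
# unknowns.
ld_train <- function(scores, groups, priors = NULL) {
  scores <- as.matrix(scores)
  groups <- as.character(groups)
  lv <- sort(unique(groups))
  g <- length(lv)
  if (g < 2L) abort("Discriminant training needs at least 2 groups")
  sizes <- as.vector(table(factor(groups, levels = lv)))
  if (is.null(priors)) {
    priors <- rep(1 / g, g)
  } else if (identical(priors, "proportional")) {
    priors <- sizes / sum(sizes)
  }
  stopifnot(length(priors) == g, all(priors > 0))
  priors <- priors / sum(priors)
  means <- rowsum(scores, groups) / sizes
  centred <- scores - means[match(groups, lv), , drop = FALSE]
  n <- nrow(scores)
  sw <- crossprod(centred) / (n - g)
  sw_inv <- tryCatch(solve(sw), error = function(e) {
    p <- ncol(sw)
    solve((1 - 1e-8) * sw + 1e-8 * diag(diag(sw) + 1e-300, p))
  })
  list(labels = lv, means = means, sw_inv = sw_inv, log_priors = log(priors))
}

ld_posterior <- function(model, newdata) {
  newdata <- matrix(as.numeric(newdata), ncol = nrow(model$sw_inv))
  g <- length(model$labels)
  disc <- matrix(NA_real_, nrow(newdata), g)
  for (j in seq_len(g)) {
    mu <- model$means[j, ]
    disc[, j] <- newdata %*% (model$sw_inv %*% mu) -
      0.5 * sum(mu * (model$sw_inv %*% mu)) + model$log_priors[j]
  }
  m <- apply(disc, 1L, max)
  post <- exp(disc - m)
  post / rowSums(post)
}

#' Leave-one-out cross-validated classification
#'
#' For every specimen, the linear discriminant (group means and pooled
#' within-group covariance) is refit on the remaining `n - 1` specimens and
#' the held-out specimen is assigned to the group with the highest
#' posterior. This is the cross-validated correct-classification percentage
#' used to judge how well groups can be told apart.
#'
#' @param scores n x p score matrix (typically [retain_components()] output).
#' @param groups True group labels.
#' @param priors `NULL` for equal priors (the default: archaeological base
#'   rates are unknown), `"proportional"` for priors proportional to group
#'   sizes, or a numeric vector over sorted group labels.
#' @return An object of class `mm_classification` with `confusion` (rows =
#'   truth), `accuracy` (per-group and overall, percent), and an
#'   `assignments` tibble with per-specimen posteriors. Specimens whose
#'   removal would empty a group are skipped with a warning.
#' @export
loo_cross_validate <- function(scores, groups, priors = NULL) {
  scores <- as.matrix(scores)
  groups <- as.character(groups)
  stopifnot(nrow(scores) == length(groups))
  lv <- sort(unique(groups))
  sizes <- table(factor(groups, levels = lv))
  n <- nrow(scores)
  ids <- rownames(scores) %||% as.character(seq_len(n))

  assigned <- rep(NA_character_, n)
  post_all <- matrix(NA_real_, n, length(lv), dimnames = list(ids, lv))
  skipped <- character()
  for (i in seq_len(n)) {
    if (sizes[[groups[[i]]]] <= 1L) {
      skipped <- c(skipped, ids[[i]])
      next
    }
    model <- ld_train(scores[-i, , drop = FALSE], groups[-i], priors)
    post <- ld_posterior(model, scores[i, , drop = FALSE])
    post_all[i, model$labels] <- post
    assigned[[i]] <- model$labels[[which.max(post)]]
  }
  if (length(skipped) > 0L) {
    warn(paste0("Skipped specimen(s) whose removal empties a group: ",
                paste(skipped, collapse = ", ")))
  }
  used <- !is.na(assigned)
  confusion <- table(
    truth = factor(groups[used], levels = lv),
    assigned = factor(assigned[used], levels = lv)
  )
  acc_group <- 100 * diag(confusion) / pmax(rowSums(confusion), 1L)
  overall <- 100 * sum(diag(confusion)) / sum(confusion)
  assignments <- tibble::tibble(
    specimen_id = ids, truth = groups, assigned = assigned,
    correct = groups == assigned
  )
  assignments <- dplyr::bind_cols(
    assignments, tibble::as_tibble(post_all, .name_repair = "minimal")
  )
  structure(
    list(confusion = unclass(confusion),
         accuracy = tibble::tibble(group = c(lv, "overall"),
                                   accuracy = unname(c(acc_group, overall))),
         assignments = assignments, labels = lv, priors = priors),
    class = "mm_classification"
  )
}

#' @export
print.mm_classification <- function(x, ...) {
  ov <- x$accuracy$accuracy[x$accuracy$group == "overall"]
  cat(sprintf("<mm_classification> overall accuracy %.1f%%\n", ov))
  print(x$confusion)
  invisible(x)
}

#' @describeIn loo_cross_validate Per-specimen assignments and posteriors.
#' @param x An `mm_classification` object.
#' @param ... Unused.
#' @export
tidy.mm_classification <- function(x, ...) x$assignments

#' @describeIn loo_cross_validate Overall and per-group accuracy.
#' @export
glance.mm_classification <- function(x, ...) {
  tidyr::pivot_wider(x$accuracy, names_from = "group",
                     values_from = "accuracy")
}

#' Project unknown configurations into a fitted modern shape space
#'
#' Each unknown configuration is superimposed onto the reference consensus
#' by ordinary Procrustes analysis (translation, unit-centroid-size scaling,
#' rotation without reflection); when the reference superimposition used
#' semilandmark sliding, the unknown's semilandmarks are slid against the
#' consensus with the same specification, iterating alignment and sliding to
#' convergence. The aligned shape is then projected onto the tangent space,
#' centred by the PCA mean shape, and projected onto the eigenvectors.
#' Unknowns never influence the consensus or the eigenvectors.
#'
#' @param aligned_reference The `mm_gpa` fitted on the (modern) training
#'   sample.
#' @param space The `mm_pca` fitted on the same sample.
#' @param unknowns Coordinate tibble (`specimen_id`, `point`, `x`, `y`), an
#'   `mm_dataset`, or a K x 2 x n array of unknown configurations.
#' @param slide Sliding specification; defaults to the one stored in
#'   `aligned_reference` (possibly `NULL`).
#' @return Score matrix (unknowns x components) with specimen ids as row
#'   names.
#' @export
project_unknowns <- function(aligned_reference, space, unknowns,
                             slide = aligned_reference$slide) {
  stopifnot(inherits(aligned_reference, "mm_gpa"), inherits(space, "mm_pca"))
  arr <- if (is.array(unknowns) && length(dim(unknowns)) == 3L) unknowns
         else coord_array(unknowns)
  k <- nrow(aligned_reference$consensus)
  if (dim(arr)[1] != k) abort("Unknowns must share K with the reference")
  consensus <- aligned_reference$consensus
  be <- if (!is.null(slide)) bending_energy_model(consensus) else NULL
  n <- dim(arr)[3]
  ids <- dimnames(arr)[[3]] %||% as.character(seq_len(n))

  cvec <- as.vector(consensus); cvec <- cvec / sqrt(sum(cvec^2))
  mean_vec <- as.vector(space$mean_shape)
  out <- matrix(NA_real_, n, ncol(space$rotation),
                dimnames = list(ids, colnames(space$rotation)))
  for (i in seq_len(n)) {
    pts <- arr[, , i]
    cs <- tryCatch(centroid_size(pts), error = function(e) {
      abort(paste0("Degenerate unknown configuration: ", ids[[i]]))
    })
    pts <- centre_points(pts) / cs
    pts <- pts %*% optimal_rotation(pts, consensus)
    if (!is.null(slide)) {
      # exactly the projection used in gpa(): slide from the raw digitised
      # positions with consensus tangents, iterating only the rotation
      semi_idx <- slide$layout$point[slide$layout$role == "semi"]
      cons_tang <- semilandmark_tangents(consensus, semi_idx, slide$closed)
      raw <- pts
      for (it in seq_len(max(slide$max_outer_iterations, 5L))) {
        slid <- slide_semilandmarks(raw, be, slide, tangents = cons_tang)
        slid <- centre_points(slid) / centroid_size(slid)
        r <- optimal_rotation(slid, consensus)
        raw <- raw %*% r
        pts_new <- slid %*% r
        done <- sqrt(sum((pts_new - pts)^2)) < slide$tolerance
        pts <- pts_new
        if (done) break
      }
    }
    v <- as.vector(pts)
    v <- v - sum(v * cvec) * cvec        # tangent-space projection
    out[i, ] <- (v - mean_vec) %*% space$rotation
  }
  out
}

#' Assign unknown specimens with a linear predictive discriminant
#'
#' Trains the pooled-covariance linear discriminant on the full training
#' scores and returns posterior probabilities and maximum-posterior
#' assignments for the unknowns. Posterior ties are broken toward the first
#' group in sorted label order and flagged.
#'
#' @param scores Training score matrix.
#' @param groups Training group labels.
#' @param unknown_scores Matrix of unknown scores with the same number of
#'   columns (e.g. from [project_unknowns()], cut to the retained
#'   components).
#' @param priors As in [loo_cross_validate()].
#' @return An object of class `mm_assignment`; `tidy()` gives one row per
#'   unknown with `assigned`, a `tie` flag, and one posterior column per
#'   group.
#' @export
classify_unknowns <- function(scores, groups, unknown_scores, priors = NULL) {
  scores <- as.matrix(scores)
  unknown_scores <- as.matrix(unknown_scores)
  if (ncol(unknown_scores) != ncol(scores)) {
    abort(sprintf("Unknown scores have %d variables but training has %d",
                  ncol(unknown_scores), ncol(scores)))
  }
  model <- ld_train(scores, groups, priors)
  post <- ld_posterior(model, unknown_scores)
  colnames(post) <- model$labels
  ids <- rownames(unknown_scores) %||% as.character(seq_len(nrow(post)))
  best <- apply(post, 1L, max)
  tie <- apply(post, 1L, function(p) sum(p >= max(p) - 1e-12) > 1L)
  assigned <- model$labels[apply(post, 1L, which.max)]
  assignments <- tibble::tibble(specimen_id = ids, assigned = assigned,
                                posterior = best, tie = tie)
  assignments <- dplyr::bind_cols(
    assignments, tibble::as_tibble(post, .name_repair = "minimal")
  )
  structure(list(assignments = assignments, labels = model$labels),
            class = "mm_assignment")
}

#' @export
print.mm_assignment <- function(x, ...) {
  cat(sprintf("<mm_assignment> %d unknowns\n", nrow(x$assignments)))
  print(dplyr::count(x$assignments, .data$assigned))
  invisible(x)
}

#' @describeIn classify_unknowns Per-unknown assignment table.
#' @param x An `mm_assignment` object.
#' @param ... Unused.
#' @export
tidy.mm_assignment <- function(x, ...) x$assignments

#' Summarise assignments as counts and percentages per stratum
#'
#' Tabulates assigned groups, optionally within strata (e.g. site and/or
#' tooth), reporting raw percentages alongside a display percentage rounded
#' to the nearest integer.
#'
#' @param assignments An `mm_assignment`, or a data frame with an
#'   `assigned` column plus any stratum columns.
#' @param by Character vector of stratum columns (empty = pooled).
#' @return Tibble with stratum columns, `assigned`, `n`, `percent` (raw),
#'   and `percent_display`.
#' @export
summarize_assignments <- function(assignments, by = character()) {
  df <- if (inherits(assignments, "mm_assignment")) assignments$assignments
        else tibble::as_tibble(assignments)
  stopifnot("assigned" %in% names(df))
  counts <- if ("n" %in% names(df)) {
    dplyr::summarise(dplyr::group_by(df, dplyr::across(dplyr::all_of(c(by, "assigned")))),
                     n = sum(.data$n), .groups = "drop")
  } else {
    dplyr::count(df, dplyr::across(dplyr::all_of(c(by, "assigned"))))
  }
  out <- dplyr::mutate(
    dplyr::group_by(counts, dplyr::across(dplyr::all_of(by))),
    percent = 100 * .data$n / sum(.data$n),
    percent_display = round(100 * .data$n / sum(.data$n))
  )
  dplyr::ungroup(out)
}
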