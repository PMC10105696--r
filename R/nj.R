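#' Neighbour-joining phenogram from a distance matrix
#'
#' Standard Saitou-Nei neighbour joining: at each step the pair minimising
#' the Q criterion `Q_ij = (m - 2) d_ij - r_i - r_j` is joined and branch
#' lengths follow the rate-corrected formulas. Ties in the Q minimisation
#' are broken toward the lowest (i, j) index pair in sorted-label order, so
#' the output is deterministic. On an additive distance matrix the
#' generating tree (topology and branch lengths) is recovered exactly.
#' Negative branch lengths (possible on non-additive input such as
#' Mahalanobis distances) are clamped to zero for display; the pre-clamp
#' values are retained in the `branch_log`.
#'
#' @param distances g x g symmetric matrix with zero diagonal and
#'   non-negative entries (e.g. the `mahalanobis` element of an `mm_cva`).
#' @param labels Taxon labels; default the matrix rownames.
#' @return An object of class `pheno_tree`: `root` (nested node structure
#'   with a trifurcating root, as usual for unrooted NJ trees), `labels`,
#'   and `branch_log` (tibble of raw and clamped branch lengths).
#' @export
neighbor_joining <- function(distances, labels = NULL) {
  d <- as.matrix(distances)
  labels <- labels %||% rownames(d) %||% paste0("g", seq_len(nrow(d)))
  g <- nrow(d)
  if (g < 3L) abort("Neighbour joining needs at least 3 taxa")
  if (ncol(d) != g) abort("Distance matrix must be square")
  if (max(abs(d - t(d))) > 1e-8) abort("Distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) abort("Distance matrix diagonal must be zero")
  if (any(d < -1e-12)) abort("Distances must be non-negative")

  ord <- order(labels)
  d <- d[ord, ord, drop = FALSE]
  labels <- labels[ord]

  nodes <- lapply(labels, function(l) list(label = l, children = NULL))
  branch_log <- list()
  add_branch <- function(child, length_raw) {
    branch_log[[length(branch_log) + 1L]] <<- tibble::tibble(
      child = child_name(child), length_raw = length_raw,
      length = max(0, length_raw)
    )
    list(node = child, length = max(0, length_raw))
  }
  child_name <- function(node) {
    if (!is.null(node$label)) node$label else {
      paste0("(", paste(vapply(node$children, function(ch)
        child_name(ch$node), character(1)), collapse = ","), ")")
    }
  }

  m <- g
  while (m > 3L) {
    r <- rowSums(d)
    q <- (m - 2) * d - outer(r, r, `+`)
    diag(q) <- Inf
    # lowest (i, j) with i < j among the minima
    best <- which(q == min(q[upper.tri(q)]), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
    i <- best[1, 1]; j <- best[1, 2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- d[i, j] - li
    new_node <- list(label = NULL,
                     children = list(add_branch(nodes[[i]], li),
                                     add_branch(nodes[[j]], lj)))
    d_new <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], d_new[keep]),
               c(d_new[keep], 0))
    nodes <- c(nodes[keep], list(new_node))
    m <- m - 1L
  }
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  root <- list(label = NULL,
               children = list(add_branch(nodes[[1]], la),
                               add_branch(nodes[[2]], lb),
                               add_branch(nodes[[3]], lc)))
  structure(
    list(root = root, labels = labels,
         branch_log = dplyr::bind_rows(branch_log)),
    class = "pheno_tree"
  )
}

#' @export
print.pheno_tree <- function(x, ...) {
  cat("<pheno_tree>", format_newick(x), "\n")
  invisible(x)
}

#' @describeIn neighbor_joining Branch-length table (raw and clamped).
#' @param x A `pheno_tree` object.
#' @param ... Unused.
#' @export
tidy.pheno_tree <- function(x, ...) x$branch_log

quote_label <- function(label) {
  if (grepl("[][ \t():;,']", label)) {
    paste0("'", gsub("'", "''", label), "'")
  } else {
    label
  }
}

format_newick_node <- function(node) {
  if (!is.null(node$label)) return(quote_label(node$label))
  inner <- vapply(node$children, function(ch) {
    paste0(format_newick_node(ch$node), ":", format(ch$length, digits = 15))
  }, character(1))
  paste0("(", paste(inner, collapse = ","), ")")
}

#' Newick string of a phenogram
#'
#' @param tree A `pheno_tree`.
#' @return Newick string with branch lengths; labels containing spaces or
#'   newick metacharacters are single-quoted.
#' @export
format_newick <- function(tree) {
  stopifnot(inherits(tree, "pheno_tree"))
  paste0(format_newick_node(tree$root), ";")
}

#' Write a phenogram to a newick file
#'
#' @param tree A `pheno_tree`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  writeLines(format_newick(tree), path)
  invisible(path)
}
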