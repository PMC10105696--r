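#' Allocate semilandmarks across inter-landmark segments
#'
#' A closed outline with `n_fixed` fixed landmarks has `n_fixed` curve
#' segments, each bounded by two consecutive fixed landmarks. The `n_semi`
#' semilandmarks are split as equally as possible across segments; any
#' remainder goes to the segments with the longest template arc length
#' (ties and absent arc lengths resolve to the earliest segments).
#'
#' @param n_fixed Number of fixed landmarks (>= 3).
#' @param n_semi Total number of semilandmarks.
#' @param arc_lengths Optional numeric vector of per-segment template arc
#'   lengths used to place the remainder.
#' @return Integer vector of length `n_fixed` summing to `n_semi`.
#' @export
semilandmark_allocation <- function(n_fixed, n_semi, arc_lengths = NULL) {
  stopifnot(n_fixed >= 3L, n_semi >= 0L)
  base <- n_semi %/% n_fixed
  rem <- n_semi %% n_fixed
  alloc <- rep(base, n_fixed)
  if (rem > 0L) {
    pref <- if (is.null(arc_lengths)) {
      seq_len(n_fixed)
    } else {
      order(-arc_lengths, seq_len(n_fixed))
    }
    alloc[pref[seq_len(rem)]] <- alloc[pref[seq_len(rem)]] + 1L
  }
  alloc
}

#' Point-role layout of a landmark protocol
#'
#' Describes the digitising order of a closed-outline protocol: fixed
#' landmark 1, then the semilandmarks of segment 1, then fixed landmark 2,
#' and so on. Semilandmarks of one segment occupy contiguous indices between
#' their bounding fixed landmarks.
#'
#' @inheritParams semilandmark_allocation
#' @param allocation Optional integer vector (length `n_fixed`) giving the
#'   semilandmark count per segment; defaults to [semilandmark_allocation()].
#' @return A tibble with columns `point`, `role` (`"fixed"`/`"semi"`) and
#'   `segment` (segment index for semilandmarks, `NA` for fixed points).
#' @export
landmark_layout <- function(n_fixed = 9, n_semi = 66, allocation = NULL) {
  allocation <- allocation %||% semilandmark_allocation(n_fixed, n_semi)
  stopifnot(length(allocation) == n_fixed, sum(allocation) == n_semi)
  role <- character(0)
  segment <- integer(0)
  for (s in seq_len(n_fixed)) {
    role <- c(role, "fixed", rep("semi", allocation[s]))
    segment <- c(segment, NA_integer_, rep(s, allocation[s]))
  }
  tibble::tibble(point = seq_along(role), role = role, segment = segment)
}

#' Assemble a morphometric dataset from coordinates and metadata
#'
#' Joins long-format landmark coordinates to specimen metadata and attaches
#' the point-role layout, validating that every configuration has the same
#' number of points in the same digitising order and that every specimen has
#' exactly one metadata row.
#'
#' @param coords Coordinate tibble (`specimen_id`, `point`, `x`, `y`) from
#'   [read_tps()] or [simulate_dataset()].
#' @param metadata Metadata tibble from [read_metadata()] /
#'   [validate_metadata()].
#' @param layout Point-role layout from [landmark_layout()]; the default
#'   is the 9 fixed + 66 sliding semilandmark molar protocol when the data
#'   have 75 points per specimen, otherwise an all-fixed layout.
#' @return An object of class `mm_dataset`: a list with elements
#'   `landmarks` (coordinates joined to roles), `metadata`, and `layout`.
#'   Metadata rows without a configuration are dropped with a message.
#' @export
assemble_dataset <- function(coords, metadata, layout = NULL) {
  metadata <- validate_metadata(metadata)
  counts <- table(coords$specimen_id)
  if (length(unique(counts)) != 1L) {
    abort(paste0(
      "Configurations have heterogeneous point counts: ",
      paste(sort(unique(counts)), collapse = ", ")
    ))
  }
  k <- as.integer(counts[[1]])
  if (is.null(layout)) {
    layout <- if (k == 75L) landmark_layout(9, 66) else {
      tibble::tibble(point = seq_len(k), role = "fixed", segment = NA_integer_)
    }
  }
  if (nrow(layout) != k) {
    abort(sprintf("Layout describes %d points but configurations have %d",
                  nrow(layout), k))
  }
  ids <- unique(coords$specimen_id)
  missing_meta <- setdiff(ids, metadata$specimen_id)
  if (length(missing_meta) > 0L) {
    abort(paste0(
      "Configuration(s) without metadata: ",
      paste(missing_meta, collapse = ", ")
    ))
  }
  unmatched <- setdiff(metadata$specimen_id, ids)
  if (length(unmatched) > 0L) {
    inform(sprintf("Dropping %d metadata row(s) without configurations",
                   length(unmatched)))
    metadata <- metadata[metadata$specimen_id %in% ids, ]
  }
  metadata <- metadata[match(ids, metadata$specimen_id), ]
  landmarks <- dplyr::left_join(coords, layout, by = "point")
  structure(
    list(landmarks = landmarks, metadata = metadata, layout = layout),
    class = "mm_dataset"
  )
}

#' @export
print.mm_dataset <- function(x, ...) {
  n_fixed <- sum(x$layout$role == "fixed")
  n_semi <- sum(x$layout$role == "semi")
  cat(sprintf(
    "<mm_dataset> %d specimens, %d points (%d fixed + %d semilandmarks)\n",
    nrow(x$metadata), nrow(x$layout), n_fixed, n_semi
  ))
  print(dplyr::count(x$metadata, .data$tooth, .data$wear_class))
  invisible(x)
}

#' Restrict a dataset to the analysable wear classes of one tooth
#'
#' Teeth with little to no wear (class 0) and highly worn teeth (class 4)
#' cannot be digitised reliably because the enamel-dentine junction is not
#' (or no longer) exposed, so they are excluded for both molars. For the
#' second molar, class 3 is additionally excluded as too rare to analyse.
#' The retained classes are therefore 1-3 for m1 and 1-2 for m2.
#'
#' @param dataset An `mm_dataset`.
#' @param tooth `"m1"` or `"m2"`.
#' @param keep_classes Override of the retained wear classes (escape hatch;
#'   the default implements the rule above).
#' @return The filtered `mm_dataset` (configurations untouched); per-class
#'   removal counts are reported via `message()`.
#' @export
filter_analysis_set <- function(dataset, tooth, keep_classes = NULL) {
  stopifnot(inherits(dataset, "mm_dataset"))
  tooth <- match.arg(tooth, c("m1", "m2"))
  keep_classes <- keep_classes %||% if (tooth == "m1") 1:3 else 1:2
  md <- dataset$metadata
  in_tooth <- md$tooth == tooth
  keep <- in_tooth & md$wear_class %in% keep_classes
  dropped <- md[in_tooth & !keep, ]
  if (nrow(dropped) > 0L) {
    tab <- table(dropped$wear_class)
    inform(paste0(
      "filter_analysis_set(", tooth, "): removed ",
      paste(sprintf("%s specimen(s) of wear class %s", tab, names(tab)),
            collapse = ", ")
    ))
  }
  if (!any(keep)) {
    abort(sprintf("No %s specimens left in wear classes {%s}",
                  tooth, paste(keep_classes, collapse = ",")))
  }
  ids <- md$specimen_id[keep]
  structure(
    list(
      landmarks = dataset$landmarks[dataset$landmarks$specimen_id %in% ids, ],
      metadata = md[keep, ],
      layout = dataset$layout
    ),
    class = "mm_dataset"
  )
}

#' Coordinates of a dataset as a K x 2 x n array
#'
#' @param x An `mm_dataset` or a coordinate tibble.
#' @return Numeric array `K x 2 x n` with specimen ids as the third
#'   dimension names.
#' @export
coord_array <- function(x) {
  coords <- if (inherits(x, "mm_dataset")) x$landmarks else x
  ids <- unique(coords$specimen_id)
  k <- sum(coords$specimen_id == ids[[1]])
  arr <- array(NA_real_, c(k, 2L, length(ids)),
               dimnames = list(NULL, c("x", "y"), ids))
  for (i in seq_along(ids)) {
    df <- coords[coords$specimen_id == ids[[i]], ]
    df <- df[order(df$point), ]
    if (nrow(df) != k) abort("Heterogeneous point counts across specimens")
    arr[, 1L, i] <- df$x
    arr[, 2L, i] <- df$y
  }
  arr
}

#' Long-format tibble from a K x 2 x n coordinate array
#'
#' @param arr Array as produced by [coord_array()].
#' @param ids Optional specimen ids (defaults to the array's dimnames).
#' @return Tibble with columns `specimen_id`, `point`, `x`, `y`.
#' @export
coords_to_tibble <- function(arr, ids = NULL) {
  ids <- ids %||% dimnames(arr)[[3]] %||% as.character(seq_len(dim(arr)[3]))
  purrr::map_dfr(seq_along(ids), function(i) {
    tibble::tibble(
      specimen_id = ids[[i]],
      point = seq_len(dim(arr)[1]),
      x = arr[, 1L, i], y = arr[, 2L, i]
    )
  })
}
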