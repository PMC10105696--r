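#' Read landmark configurations from a TPS file
#'
#' Parses the flat-landmark TPS dialect written by tpsDig: records start with
#' `LM=k`, followed by `k` lines of two whitespace-separated coordinates and
#' optional `IMAGE=`, `ID=`, `SCALE=` and `COMMENT=` lines. Keys are matched
#' case-insensitively and both LF and CRLF line endings are accepted.
#' Coordinates are kept exactly as digitised (y-up, no image-axis flip).
#'
#' @param path Path to a TPS file.
#' @param apply_scale If `TRUE` (default) coordinates of a record carrying a
#'   `SCALE=` line are multiplied by that factor, converting pixel coordinates
#'   to millimetres. Records without a scale line are kept in their original
#'   units and flagged: their ids are returned in the `unit_unknown` attribute
#'   and a warning is raised (archaeological photographs may lack a scale).
#' @return A tibble with columns `specimen_id`, `point` (1-based index in
#'   digitising order), `x`, `y`, one row per landmark, specimens in file
#'   order. Attribute `unit_unknown` lists ids lacking a scale factor when
#'   `apply_scale = TRUE`.
#' @seealso [write_tps()], [assemble_dataset()]
#' @export
read_tps <- function(path, apply_scale = TRUE) {
  if (!file.exists(path)) {
    abort(paste0("TPS file not found: ", path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)

  recs <- list()
  cur <- NULL
  n_expected <- 0L
  unit_unknown <- character()
  ordinal <- 0L

  flush_record <- function(cur, ordinal) {
    if (nrow(cur$coords) != cur$n_expected) {
      abort(sprintf(
        "TPS record %d declares LM=%d but contains %d coordinate rows",
        ordinal, cur$n_expected, nrow(cur$coords)
      ))
    }
    id <- cur$id
    if (is.null(id) && !is.null(cur$image)) {
      id <- sub("\\.[A-Za-z0-9]+$", "", basename(cur$image))
    }
    if (is.null(id)) id <- as.character(ordinal)
    scale <- cur$scale
    cur$coords$specimen_id <- id
    list(id = id, coords = cur$coords, scale = scale)
  }

  out <- list()
  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (line == "") next
    key <- toupper(sub("=.*$", "", line))
    if (grepl("^[A-Z]+=", toupper(line)) && key %in%
          c("LM", "ID", "IMAGE", "SCALE", "COMMENT", "CURVES", "POINTS")) {
      val <- sub("^[A-Za-z]+=", "", line)
      if (key == "LM") {
        if (!is.null(cur)) {
          ordinal <- ordinal + 1L
          out[[length(out) + 1L]] <- flush_record(cur, ordinal)
        }
        k <- suppressWarnings(as.integer(val))
        if (is.na(k) || k < 0L) {
          abort(sprintf("Invalid LM= count on line %d", i))
        }
        cur <- list(
          n_expected = k,
          coords = tibble::tibble(point = integer(), x = double(), y = double()),
          id = NULL, image = NULL, scale = NULL
        )
      } else if (key == "ID") {
        cur$id <- trimws(val)
      } else if (key == "IMAGE") {
        cur$image <- trimws(val)
      } else if (key == "SCALE") {
        s <- suppressWarnings(as.numeric(val))
        if (is.na(s)) abort(sprintf("Non-numeric SCALE on line %d", i))
        cur$scale <- s
      } else if (key %in% c("CURVES", "POINTS")) {
        abort("TPS CURVES=/POINTS= records are not supported; export flat landmarks")
      }
      # COMMENT= ignored
    } else {
      if (is.null(cur)) {
        abort(sprintf("Coordinate data before any LM= header on line %d", i))
      }
      parts <- strsplit(line, "[[:space:]]+")[[1]]
      xy <- suppressWarnings(as.numeric(parts))
      if (length(xy) != 2L || anyNA(xy)) {
        abort(sprintf("Non-numeric or malformed coordinate row on line %d", i))
      }
      cur$coords <- tibble::add_row(
        cur$coords, point = nrow(cur$coords) + 1L, x = xy[1], y = xy[2]
      )
    }
  }
  if (!is.null(cur)) {
    ordinal <- ordinal + 1L
    out[[length(out) + 1L]] <- flush_record(cur, ordinal)
  }
  if (length(out) == 0L) abort("No TPS records found")

  ids <- vapply(out, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    abort(paste0(
      "Duplicate specimen id(s) in TPS file: ",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }

  coords <- purrr::map_dfr(out, function(rec) {
    df <- rec$coords
    if (apply_scale) {
      if (!is.null(rec$scale)) {
        df$x <- df$x * rec$scale
        df$y <- df$y * rec$scale
      } else {
        unit_unknown <<- c(unit_unknown, rec$id)
      }
    }
    df[, c("specimen_id", "point", "x", "y")]
  })
  if (!all(is.finite(coords$x)) || !all(is.finite(coords$y))) {
    abort("Non-finite coordinates in TPS file")
  }
  if (apply_scale && length(unit_unknown) > 0L) {
    warn(paste0(
      "No SCALE= factor for ", length(unit_unknown),
      " record(s); coordinates kept in original units (see attr 'unit_unknown')"
    ))
  }
  attr(coords, "unit_unknown") <- unit_unknown
  coords
}

#' Write landmark configurations to a TPS file
#'
#' Writes the flat-landmark TPS dialect read by [read_tps()]; the pair
#' round-trips coordinates exactly (17 significant digits).
#'
#' @param coords A tibble with columns `specimen_id`, `point`, `x`, `y`
#'   (as returned by [read_tps()] or [simulate_dataset()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(coords, path) {
  stopifnot(all(c("specimen_id", "point", "x", "y") %in% names(coords)))
  if (nrow(coords) == 0L) abort("No configurations to write")
  ids <- unique(coords$specimen_id)
  con_lines <- unlist(lapply(ids, function(id) {
    df <- coords[coords$specimen_id == id, ]
    df <- df[order(df$point), ]
    c(
      sprintf("LM=%d", nrow(df)),
      sprintf("%.17g %.17g", df$x, df$y),
      sprintf("ID=%s", id)
    )
  }))
  writeLines(con_lines, path)
  invisible(path)
}
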