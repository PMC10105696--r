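meta_required_cols <- c(
  "specimen_id", "tooth", "wear_class", "subspecies", "status",
  "sex", "population", "provenance"
)

#' Read and validate a specimen metadata table
#'
#' The metadata CSV carries one row per specimen with the factors the
#' analyses stratify on: tooth (`m1`/`m2`), ordinal wear class (0-4),
#' subspecies (`tarandus` = mountain reindeer, `fennicus` = forest reindeer,
#' or `unknown`), status (`wild_mountain`, `wild_forest`, `domestic`,
#' `unknown`), sex (`F`/`M`/`ND`), a free-text population label, and
#' provenance (`modern` or `archaeological`).
#'
#' Validation enforces the biological constraints of the system: wild forest
#' reindeer are *R. t. fennicus* and both domestic and wild mountain reindeer
#' are *R. t. tarandus*, so a `wild_forest`/`tarandus` row (or
#' `domestic`/`fennicus`, etc.) is rejected. Only archaeological specimens may
#' carry `unknown` subspecies/status or `ND` sex introduced by mapping
#' unrecognised tokens; for modern rows an unrecognised token is an error.
#'
#' @param path Path to a UTF-8 comma-separated file with a header containing
#'   at least the columns named above. Extra columns are kept.
#' @return A validated tibble with typed columns (`wear_class` integer, the
#'   categorical columns as character vectors restricted to their domains).
#' @export
read_metadata <- function(path) {
  # everything as character: tokens like "F" or "NA" must not be guessed
  # into logicals/missing values before validation
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  validate_metadata(df)
}

#' Validate a metadata table already in memory
#'
#' @param df A data frame with the columns described in [read_metadata()].
#' @return The validated, typed tibble.
#' @export
validate_metadata <- function(df) {
  df <- tibble::as_tibble(df)
  missing <- setdiff(meta_required_cols, names(df))
  if (length(missing) > 0L) {
    abort(paste0("Metadata is missing column(s): ", paste(missing, collapse = ", ")))
  }
  df$specimen_id <- as.character(df$specimen_id)
  if (anyDuplicated(df$specimen_id)) {
    abort("Duplicate specimen_id in metadata")
  }
  df$tooth <- tolower(as.character(df$tooth))
  bad <- setdiff(unique(df$tooth), c("m1", "m2"))
  if (length(bad) > 0L) {
    abort(paste0("Unrecognised tooth value(s): ", paste(bad, collapse = ", ")))
  }
  wc <- suppressWarnings(as.integer(df$wear_class))
  if (anyNA(wc) || any(wc < 0L | wc > 4L)) {
    abort("wear_class must be an integer between 0 and 4")
  }
  df$wear_class <- wc
  df$provenance <- tolower(as.character(df$provenance))
  bad <- setdiff(unique(df$provenance), c("modern", "archaeological"))
  if (length(bad) > 0L) {
    abort(paste0("Unrecognised provenance value(s): ", paste(bad, collapse = ", ")))
  }
  arch <- df$provenance == "archaeological"

  map_domain <- function(x, domain, fallback, col) {
    # a logical column can only arise from "F" being parsed as FALSE
    if (is.logical(x) && identical(col, "sex")) x <- ifelse(x, "T", "F")
    x <- as.character(x)
    ok <- x %in% domain
    if (any(!ok & !arch)) {
      abort(sprintf(
        "Unrecognised %s value(s) for modern specimen(s): %s",
        col, paste(unique(x[!ok & !arch]), collapse = ", ")
      ))
    }
    x[!ok] <- fallback   # archaeological rows only
    x
  }
  df$subspecies <- map_domain(df$subspecies, c("tarandus", "fennicus", "unknown"),
                              "unknown", "subspecies")
  df$status <- map_domain(df$status,
                          c("wild_mountain", "wild_forest", "domestic", "unknown"),
                          "unknown", "status")
  df$sex <- map_domain(df$sex, c("F", "M", "ND"), "ND", "sex")
  df$population <- as.character(df$population)

  contradiction <- (df$status == "wild_forest" & df$subspecies != "fennicus") |
    (df$status %in% c("domestic", "wild_mountain") & df$subspecies != "tarandus")
  if (any(contradiction)) {
    abort(paste0(
      "Status/subspecies contradiction for specimen(s): ",
      paste(df$specimen_id[contradiction], collapse = ", ")
    ))
  }
  df
}
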