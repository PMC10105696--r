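#' Configuration for the end-to-end analysis pipeline
#'
#' @param tps Path to the TPS landmark file (modern and archaeological
#'   specimens together).
#' @param metadata Path to the metadata CSV, or a metadata data frame.
#' @param tooth `"m1"` or `"m2"`.
#' @param grouping Metadata column used for group statistics and
#'   classification (`"subspecies"`, `"status"`, `"population"`, `"sex"`).
#' @param wear_classes Wear classes to analyse; `NULL` applies the standard
#'   exclusion rule (1-3 for m1, 1-2 for m2) via [filter_analysis_set()].
#' @param retention Cumulative variance proportion retained before CVA.
#' @param n_perm Permutations for the shape variance decomposition and the
#'   allometry test.
#' @param seed Seed stamped into every output.
#' @param output_dir Directory for result tables, trees and the log.
#' @param slide Slide semilandmarks during superimposition (default `TRUE`
#'   when the layout has semilandmarks).
#' @return A `run_config` list.
#' @export
run_config <- function(tps, metadata, tooth = "m1",
                       grouping = "subspecies", wear_classes = NULL,
                       retention = 0.95, n_perm = 199L, seed = 1L,
                       output_dir = "molargm_results", slide = TRUE) {
  tooth <- match.arg(tooth, c("m1", "m2"))
  stopifnot(retention > 0, retention <= 1)
  structure(
    list(tps = tps, metadata = metadata, tooth = tooth, grouping = grouping,
         wear_classes = wear_classes, retention = retention,
         n_perm = as.integer(n_perm), seed = as.integer(seed),
         output_dir = output_dir, slide = isTRUE(slide)),
    class = "run_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys match the arguments of [run_config()].
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

pipeline_stage <- function(name, log, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e) {
    abort(paste0("Pipeline stage '", name, "' failed: ",
                 conditionMessage(e)))
  })
  log(sprintf("%s: done in %.2fs", name, as.numeric(Sys.time() - t0,
                                                    units = "secs")))
  res
}

#' Run the full analysis pipeline
#'
#' Orchestrates the complete workflow for one tooth: inclusion filtering by
#' wear class, Procrustes superimposition with semilandmark sliding, and
#' per-wear-class size tests, PCA, shape variance decomposition, CVA with
#' leave-one-out cross-validation, Mahalanobis neighbour-joining phenogram,
#' allometry regression, and linear discriminant assignment of
#' archaeological specimens projected into the modern shape space. Tables
#' are written as CSV with a JSON parameter sidecar; trees as newick; a
#' plain-text log records input and dropped counts, seeds and runtimes.
#'
#' @param config A [run_config()].
#' @return Invisibly, a named list of per-stratum result bundles plus the
#'   pooled archaeological assignment summary.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$output_dir, "run.log")
  log_lines <- character()
  log <- function(msg) {
    log_lines <<- c(log_lines, msg)
    inform(msg)
  }
  version <- as.character(utils::packageVersion("molargm"))
  log(sprintf("molargm %s | tooth %s | grouping %s | seed %d",
              version, config$tooth, config$grouping, config$seed))

  coords <- pipeline_stage("read_tps", log, read_tps(config$tps))
  metadata <- pipeline_stage("read_metadata", log, {
    if (is.character(config$metadata)) read_metadata(config$metadata)
    else validate_metadata(config$metadata)
  })
  dataset <- pipeline_stage("assemble", log,
                            assemble_dataset(coords, metadata))
  log(sprintf("assembled %d specimens", nrow(dataset$metadata)))

  modern <- dataset$metadata$provenance == "modern"
  arch_ids <- dataset$metadata$specimen_id[!modern]
  modern_ds <- structure(
    list(landmarks = dataset$landmarks[
           dataset$landmarks$specimen_id %in%
             dataset$metadata$specimen_id[modern], ],
         metadata = dataset$metadata[modern, ], layout = dataset$layout),
    class = "mm_dataset"
  )
  filtered <- pipeline_stage(
    "filter_analysis_set", log,
    filter_analysis_set(modern_ds, config$tooth, config$wear_classes)
  )
  log(sprintf("retained %d modern %s specimens in wear classes {%s}",
              nrow(filtered$metadata), config$tooth,
              paste(sort(unique(filtered$metadata$wear_class)),
                    collapse = ",")))

  has_semi <- any(dataset$layout$role == "semi")
  slide <- if (config$slide && has_semi) sliding_spec(dataset$layout) else NULL

  strata <- sort(unique(filtered$metadata$wear_class))
  results <- list()
  arch_assignments <- list()
  for (wc in strata) {
    tag <- sprintf("%s_class%d", config$tooth, wc)
    ids <- filtered$metadata$specimen_id[filtered$metadata$wear_class == wc]
    if (length(ids) < 4L) {
      warn(sprintf("Stratum %s has %d specimens; skipped", tag, length(ids)))
      next
    }
    strat <- structure(
      list(landmarks = filtered$landmarks[
             filtered$landmarks$specimen_id %in% ids, ],
           metadata = filtered$metadata[
             filtered$metadata$wear_class == wc, ],
           layout = filtered$layout),
      class = "mm_dataset"
    )
    groups <- strat$metadata[[config$grouping]]
    if (length(unique(groups)) < 2L) {
      warn(sprintf("Stratum %s has a single %s level; skipped",
                   tag, config$grouping))
      next
    }
    aligned <- pipeline_stage(paste0(tag, ":gpa"), log,
                              gpa(strat, slide = slide))
    sizes <- pipeline_stage(paste0(tag, ":size_tests"), log,
                            size_tests(aligned, config$grouping))
    space <- pipeline_stage(paste0(tag, ":pca"), log, pca_shapes(aligned))
    vdec <- pipeline_stage(
      paste0(tag, ":variance_decomposition"), log,
      variance_decomposition(aligned, config$grouping,
                             n_perm = config$n_perm, seed = config$seed)
    )
    kept <- retain_components(space, config$retention)
    cva <- pipeline_stage(paste0(tag, ":cva"), log,
                          cva_fit(kept$scores, groups))
    loo <- pipeline_stage(paste0(tag, ":loo"), log,
                          loo_cross_validate(kept$scores, groups))
    allo <- pipeline_stage(
      paste0(tag, ":allometry"), log,
      allometry_regression(aligned, n_perm = config$n_perm,
                           seed = config$seed)
    )
    tree <- NULL
    if (length(cva$labels) >= 3L) {
      tree <- pipeline_stage(paste0(tag, ":nj"), log,
                             neighbor_joining(cva$mahalanobis))
      write_newick(tree, file.path(config$output_dir,
                                   paste0(tag, "_nj.nwk")))
    }

    arch_meta <- dataset$metadata[
      !modern & dataset$metadata$tooth == config$tooth &
        dataset$metadata$wear_class == wc, ]
    assign_tab <- NULL
    if (nrow(arch_meta) > 0L) {
      arch_arr <- coord_array(dataset$landmarks[
        dataset$landmarks$specimen_id %in% arch_meta$specimen_id, ])
      u_scores <- pipeline_stage(
        paste0(tag, ":project_unknowns"), log,
        project_unknowns(aligned, space, arch_arr, slide = slide)
      )
      assign_res <- pipeline_stage(
        paste0(tag, ":classify_unknowns"), log,
        classify_unknowns(kept$scores, groups,
                          u_scores[, seq_len(kept$n_retained),
                                   drop = FALSE])
      )
      assign_tab <- dplyr::left_join(
        tidy(assign_res),
        arch_meta[, c("specimen_id", "population", "tooth", "wear_class")],
        by = "specimen_id"
      )
      arch_assignments[[tag]] <- assign_tab
    }

    prefix <- file.path(config$output_dir, tag)
    readr::write_csv(tidy(sizes), paste0(prefix, "_size_wilcoxon.csv"))
    readr::write_csv(glance(sizes), paste0(prefix, "_size_anova.csv"))
    readr::write_csv(tidy(space), paste0(prefix, "_pca.csv"))
    readr::write_csv(score_table(space), paste0(prefix, "_scores.csv"))
    readr::write_csv(tidy(vdec), paste0(prefix, "_variance_decomposition.csv"))
    readr::write_csv(loo$accuracy, paste0(prefix, "_cva_accuracy.csv"))
    readr::write_csv(tidy(cva), paste0(prefix, "_mahalanobis.csv"))
    readr::write_csv(tidy(allo), paste0(prefix, "_allometry.csv"))
    if (!is.null(assign_tab)) {
      readr::write_csv(assign_tab, paste0(prefix, "_assignments.csv"))
    }
    jsonlite::write_json(
      list(tag = tag, seed = config$seed, n = length(ids),
           n_retained = kept$n_retained, retention = config$retention,
           n_perm = config$n_perm, version = version,
           slid = !is.null(slide)),
      paste0(prefix, "_params.json"), auto_unbox = TRUE
    )
    results[[tag]] <- list(
      aligned = aligned, sizes = sizes, pca = space, variance = vdec,
      cva = cva, loo = loo, allometry = allo, tree = tree,
      assignments = assign_tab
    )
  }

  if (length(arch_assignments) > 0L) {
    all_assign <- dplyr::bind_rows(arch_assignments)
    site_summary <- summarize_assignments(all_assign,
                                          by = c("population", "tooth"))
    pooled <- summarize_assignments(all_assign)
    readr::write_csv(site_summary,
                     file.path(config$output_dir, "assignments_by_site.csv"))
    readr::write_csv(pooled,
                     file.path(config$output_dir, "assignments_pooled.csv"))
    results$site_summary <- site_summary
    results$pooled_summary <- pooled
    log(sprintf("assigned %d archaeological specimens", nrow(all_assign)))
  } else if (length(arch_ids) > 0L) {
    warn("Archaeological specimens present but none fell in analysed strata")
  }

  writeLines(log_lines, log_path)
  invisible(results)
}
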