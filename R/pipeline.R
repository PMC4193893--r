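#' Run the full measurement chain on one pre/post pair
#'
#' Executes, in order: gantry-tilt correction of the post-op volume,
#' skull thresholding of both volumes, rigid registration of the pre-op
#' to the post-op skull, spline resampling of the pre-op volume onto the
#' post-op grid, brain segmentation (post-op) and inner-table brain
#' derivation (pre-op), baseline location, the displacement field and
#' its maximum, the Flint measure, herniated volume, and both area
#' estimates. Per-stage failures are recorded and the summary carries
#' missing-value markers rather than aborting the case.
#'
#' @param pre,post `scan_volume` objects or file paths to NIfTI volumes.
#' @param config parameter list, see [default_config()].
#' @param location craniectomy location label (`"bifrontal"`,
#'   `"unilateral"` or `NA`), carried into the summary.
#' @param case_id identifier carried into the summary.
#' @param out_dir optional directory; when given, masks, the transform,
#'   the displacement-field table, the summary and a parameter log are
#'   written there.
#' @return A `case_result` list: `summary` (one-row data frame with
#'   `case_id`, `location`, `dy_max_mm`, `dV_ml`, `y_flint_mm`,
#'   `area_hw_mm2`, `area_mesh_mm2`, `flags`, `status`), plus the
#'   intermediate objects (`registration`, `baseline`, `field`, masks).
#' @export
run_case <- function(pre, post, config = default_config(), location = NA,
                     case_id = "case", out_dir = NULL) {
  if (is.character(pre)) pre <- read_volume(pre)
  if (is.character(post)) post <- read_volume(post)
  flags <- character(0)
  fail <- function(stage, e) {
    flags <<- c(flags, paste0(stage, ": ", conditionMessage(e)))
    NULL
  }

  if (post$gantry_tilt_deg != 0) post <- correct_gantry_tilt(post)
  if (pre$gantry_tilt_deg != 0) pre <- correct_gantry_tilt(pre)

  post_skull <- tryCatch(skull_mask(post, config$skull_threshold),
                         error = function(e) fail("skull_post", e))
  pre_skull_native <- tryCatch(skull_mask(pre, config$skull_threshold),
                               error = function(e) fail("skull_pre", e))

  reg <- NULL
  pre_skull <- NULL
  pre_brain <- NULL
  if (!is.null(post_skull) && !is.null(pre_skull_native)) {
    reg <- tryCatch(rigid_register(post_skull, pre_skull_native),
                    error = function(e) fail("register", e))
  }
  if (!is.null(reg)) {
    # masks are carried to the post grid nearest-neighbour: binarity is
    # preserved and no systematic surface erosion is introduced (the
    # brain/bone threshold does not sit at the bone/air half-level)
    pre_skull <- resample_mask(pre_skull_native, reg$transform, post)
    pre_brain_native <- tryCatch(brain_from_inner_table(pre_skull_native),
                                 error = function(e) fail("pre_brain", e))
    if (!is.null(pre_brain_native))
      pre_brain <- resample_mask(pre_brain_native, reg$transform, post)
  }

  post_brain <- tryCatch(segment_brain(post, config),
                         error = function(e) fail("segment", e))

  baseline <- NULL
  if (!is.null(pre_skull) && !is.null(post_skull))
    baseline <- tryCatch(locate_baseline(pre_skull, post_skull),
                         error = function(e) fail("baseline", e))

  field <- NULL
  y_flint <- NA_real_
  dy_max <- NA_real_
  if (!is.null(baseline) && !is.null(pre_brain) && !is.null(post_brain)) {
    pre_edges <- extract_edge(pre_brain)
    post_edges <- extract_edge(post_brain)
    field <- tryCatch(
      displacement_field(pre_edges, post_edges, baseline,
                         config$station_spacing),
      error = function(e) fail("field", e))
    if (!is.null(field)) dy_max <- field$dy_max
    y_flint <- tryCatch(as.numeric(flint_displacement(post_edges, baseline)),
                        error = function(e) { fail("flint", e); NA_real_ })
  }

  dV <- NA_real_
  if (!is.null(pre_brain) && !is.null(post_brain)) {
    dV <- herniated_volume(pre_brain, post_brain)
    if (attr(dV, "negative")) flags <- c(flags, "dV: negative")
    dV <- as.numeric(dV)
  }
  a_hw <- if (!is.null(baseline)) area_height_width(baseline) else NA_real_
  a_mesh <- NA_real_
  if (!is.null(pre_skull) && !is.null(post_skull)) {
    am <- tryCatch(area_mesh(pre_skull, post_skull),
                   error = function(e) fail("area_mesh", e))
    if (!is.null(am)) {
      if (attr(am, "degenerate")) flags <- c(flags, "area_mesh: degenerate")
      a_mesh <- as.numeric(am)
    }
  }

  summary <- data.frame(
    case_id = case_id, location = as.character(location),
    dy_max_mm = dy_max, dV_ml = dV, y_flint_mm = y_flint,
    area_hw_mm2 = a_hw, area_mesh_mm2 = a_mesh,
    flags = paste(flags, collapse = "; "),
    status = if (length(flags)) 1L else 0L,
    stringsAsFactors = FALSE)

  res <- structure(list(summary = summary, registration = reg,
                        baseline = baseline, field = field,
                        pre_brain = pre_brain, post_brain = post_brain,
                        pre_skull = pre_skull, post_skull = post_skull),
                   class = "case_result")
  if (!is.null(out_dir)) write_case_outputs(res, config, out_dir)
  res
}

write_case_outputs <- function(res, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(res$summary, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  if (!is.null(res$field))
    utils::write.csv(res$field$samples,
                     file.path(out_dir, "displacement_field.csv"),
                     row.names = FALSE)
  if (!is.null(res$registration))
    utils::write.table(as_affine_matrix(res$registration$transform),
                       file.path(out_dir, "transform.txt"),
                       row.names = FALSE, col.names = FALSE)
  if (!is.null(res$pre_brain))
    write_mask(res$pre_brain, file.path(out_dir, "pre_brain.nii.gz"))
  if (!is.null(res$post_brain))
    write_mask(res$post_brain, file.path(out_dir, "post_brain.nii.gz"))
  cfg <- config[!vapply(config, is.null, logical(1))]
  yaml::write_yaml(cfg, file.path(out_dir, "parameters.yaml"))
  invisible(out_dir)
}

#' @export
print.case_result <- function(x, ...) {
  print(x$summary)
  invisible(x)
}

#' Aggregate statistics over a cohort summary table
#'
#' Computes the comparison layer on a per-case summary table: Pearson
#' correlations (dV vs dy_max, dV vs area, dy_max vs area), Welch tests
#' by location for dy_max, dV and area, the multiple correlation of dV
#' on dy_max and area, and per-location box summaries. Comparisons whose
#' preconditions fail (fewer than 2 cases per group, constant input) are
#' skipped with a warning.
#'
#' @param summaries data frame with columns `dy_max_mm`, `dV_ml`,
#'   `area_hw_mm2` and `location`.
#' @return A list of `stat_result` objects and box summaries.
#' @export
cohort_stats <- function(summaries) {
  s <- summaries[stats::complete.cases(
    summaries[, c("dy_max_mm", "dV_ml", "area_hw_mm2")]), ]
  out <- list()
  try_stat <- function(name, expr) {
    r <- tryCatch(expr, error = function(e) {
      warning(name, " skipped: ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (!is.null(r)) out[[name]] <<- r
  }
  if (nrow(s) >= 3) {
    try_stat("pearson_dV_dymax", pearson_r(s$dy_max_mm, s$dV_ml))
    try_stat("pearson_dV_area", pearson_r(s$area_hw_mm2, s$dV_ml))
    try_stat("pearson_dymax_area", pearson_r(s$area_hw_mm2, s$dy_max_mm))
  }
  if (nrow(s) >= 4)
    try_stat("multiple_R", multiple_regression_R(s$dV_ml, s$dy_max_mm,
                                                 s$area_hw_mm2))
  groups <- split(s, s$location)
  if (length(groups) == 2 && all(vapply(groups, nrow, 1L) >= 2)) {
    g1 <- groups[[1]]; g2 <- groups[[2]]
    try_stat("welch_dymax", welch_t(g1$dy_max_mm, g2$dy_max_mm))
    try_stat("welch_dV", welch_t(g1$dV_ml, g2$dV_ml))
    try_stat("welch_area", welch_t(g1$area_hw_mm2, g2$area_hw_mm2))
    out$group_order <- names(groups)
  } else if (length(groups) > 0) {
    warning("group comparisons skipped: need 2 locations with >= 2 cases each",
            call. = FALSE)
  }
  out$box_dymax <- lapply(groups, function(g) box_summary(g$dy_max_mm))
  out$box_dV <- lapply(groups, function(g) box_summary(g$dV_ml))
  out$box_area <- lapply(groups, function(g) box_summary(g$area_hw_mm2))
  out
}

#' Run a cohort of cases and aggregate the statistics
#'
#' @param manifest data frame with columns `case_id`, `pre_path`,
#'   `post_path`, `location` (a delimited cohort manifest read with
#'   [utils::read.csv()] works directly).
#' @param config parameter list, see [default_config()].
#' @param out_dir optional output directory; per-case subdirectories and
#'   the cohort summary table are written there.
#' @return A list: `summaries` (one row per case) and `stats` (from
#'   [cohort_stats()], NULL when fewer than 3 complete cases).
#' @export
run_cohort <- function(manifest, config = default_config(), out_dir = NULL) {
  stopifnot(all(c("case_id", "pre_path", "post_path") %in% names(manifest)))
  if (anyDuplicated(manifest$case_id))
    stop("case_id must be unique within a cohort manifest")
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    r <- manifest[i, ]
    loc <- if ("location" %in% names(manifest)) r$location else NA
    cd <- if (is.null(out_dir)) NULL else file.path(out_dir, r$case_id)
    run_case(r$pre_path, r$post_path, config, location = loc,
             case_id = r$case_id, out_dir = cd)$summary
  })
  summaries <- do.call(rbind, rows)
  stats <- if (sum(stats::complete.cases(
    summaries[, c("dy_max_mm", "dV_ml", "area_hw_mm2")])) >= 3)
    cohort_stats(summaries) else NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(summaries, file.path(out_dir, "cohort_summary.csv"),
                     row.names = FALSE)
  }
  list(summaries = summaries, stats = stats)
}
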