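#' Configuration for a longitudinal subject run
#'
#' Bundles everything needed to process one subject end to end:
#' decomposition method, per-timepoint inputs (in-memory `echo_series`
#' objects or directories written by [write_dataset()]), segmentation
#' parameters and exclusion masks. The species preset fixes the snake
#' vertex count (120 mouse-scale, 200 human-scale) unless overridden.
#'
#' @param subject_id Identifier used in reports.
#' @param species `"mouse"` or `"human"`.
#' @param method `"3pt"` (three-echo) or `"2pt"` (dual-echo) Dixon
#'   decomposition.
#' @param timepoints List, one entry per timepoint: an `echo_series` or
#'   `list(path=, name=)` referencing a written dataset.
#' @param timepoint_labels Character labels; default `"t1"`, `"t2"`, ...
#' @param snake A [snake_params()]; default depends on `species`.
#' @param exclusions Optional list of logical arrays (one per timepoint,
#'   or a single array recycled to all timepoints, e.g. a prosthesis
#'   region excluded at every examination).
#' @param slice_range Optional slice indices to analyze.
#' @param ff_threshold Adipose classification threshold.
#' @param seed Seed recorded in the audit trail.
#' @param group Optional free-text group/therapy/response label.
#' @param out_dir Optional directory for CSV/JSON reports.
#' @return An object of class `run_config`.
#' @export
run_config <- function(subject_id, species = c("mouse", "human"),
                       method = c("3pt", "2pt"), timepoints,
                       timepoint_labels = NULL, snake = NULL,
                       exclusions = NULL, slice_range = NULL,
                       ff_threshold = 0.5, seed = 1L,
                       group = NA_character_, out_dir = NULL) {
  species <- match.arg(species)
  method <- match.arg(method)
  stopifnot(is.list(timepoints), length(timepoints) >= 1L)
  if (is.null(timepoint_labels))
    timepoint_labels <- paste0("t", seq_along(timepoints))
  stopifnot(length(timepoint_labels) == length(timepoints))
  if (anyDuplicated(timepoint_labels)) stop("duplicate timepoint labels")
  if (is.null(snake))
    snake <- snake_params(n_vertices = if (species == "mouse") 120L else 200L)
  if (!is.null(exclusions) && !is.list(exclusions))
    exclusions <- rep(list(exclusions), length(timepoints))
  if (!is.null(exclusions))
    stopifnot(length(exclusions) == length(timepoints))
  # fail fast on missing files
  missing <- character(0)
  for (tp in timepoints) {
    if (inherits(tp, "echo_series")) next
    if (is.list(tp) && !is.null(tp$path)) {
      sidecar <- file.path(tp$path, paste0(tp$name %||% "phantom", ".json"))
      if (!file.exists(sidecar)) missing <- c(missing, sidecar)
    } else stop("each timepoint must be an echo_series or list(path=, name=)")
  }
  if (length(missing))
    stop("missing timepoint files:\n  ", paste(missing, collapse = "\n  "))
  structure(list(subject_id = subject_id, species = species,
                 method = method, timepoints = timepoints,
                 timepoint_labels = timepoint_labels, snake = snake,
                 exclusions = exclusions, slice_range = slice_range,
                 ff_threshold = ff_threshold, seed = as.integer(seed),
                 group = group, out_dir = out_dir),
            class = "run_config")
}

#' Run the full pipeline for one subject
#'
#' For every timepoint: decompose the echo series into water/fat maps,
#' segment the body compartments, and quantify volumes and caudocranial
#' profiles; then express follow-up volumes as percent change from
#' baseline. Deterministic: re-running the same configuration reproduces
#' identical reports.
#'
#' @param config A [run_config()].
#' @return An object of class `subject_report`: `volumes` (tibble across
#'   timepoints), `profiles`, `changes` (empty when only one timepoint),
#'   `timeline`, `segmentations`, and an `audit` record (package version,
#'   seed, parameters).
#' @export
run_subject <- function(config) {
  stopifnot(inherits(config, "run_config"))
  nt <- length(config$timepoints)
  vols <- list(); profs <- list(); segs <- list()
  for (t in seq_len(nt)) {
    tp <- config$timepoints[[t]]
    series <- if (inherits(tp, "echo_series")) tp
      else read_dataset(tp$path, tp$name %||% "phantom")$series
    fw <- switch(config$method,
                 "3pt" = decompose_three_point(series),
                 "2pt" = decompose_two_point(series))
    excl <- if (!is.null(config$exclusions)) config$exclusions[[t]] else NULL
    seg <- segment_volume(fw, params = config$snake, exclusions = excl,
                          slice_range = config$slice_range,
                          ff_threshold = config$ff_threshold)
    v <- compartment_volumes(seg)
    v$timepoint <- config$timepoint_labels[t]
    p <- axial_profile(seg)
    p$timepoint <- config$timepoint_labels[t]
    vols[[t]] <- v; profs[[t]] <- p; segs[[t]] <- seg
  }
  volumes <- dplyr::bind_rows(vols)
  wide <- volumes |>
    dplyr::select("timepoint", "compartment", "volume_mm3") |>
    tidyr::pivot_wider(names_from = "compartment",
                       values_from = "volume_mm3")
  wide$total_fat <- wide$VAT + wide$SCAT
  timeline <- subject_timeline(config$subject_id, config$species,
                               wide, group = config$group)
  changes <- if (nt >= 2L) build_change_table(timeline) else
    tibble::tibble()
  audit <- list(package = "adipoquant",
                version = as.character(utils::packageVersion("adipoquant")),
                seed = config$seed, method = config$method,
                snake = unclass(config$snake),
                ff_threshold = config$ff_threshold,
                slice_range = config$slice_range)
  report <- structure(
    list(subject_id = config$subject_id, volumes = volumes,
         profiles = dplyr::bind_rows(profs), changes = changes,
         timeline = timeline, segmentations = segs, audit = audit),
    class = "subject_report")
  if (!is.null(config$out_dir)) write_subject_report(report, config$out_dir)
  report
}

#' Write a subject report to disk
#'
#' Deterministic CSV/JSON output (no timestamps), so re-running the same
#' configuration produces byte-identical files.
#'
#' @param report A `subject_report`.
#' @param out_dir Existing directory.
#' @return Invisibly, the files written.
#' @export
write_subject_report <- function(report, out_dir) {
  stopifnot(inherits(report, "subject_report"))
  if (!dir.exists(out_dir)) stop("output directory does not exist: ", out_dir)
  base <- file.path(out_dir, paste0("subject_", report$subject_id))
  f1 <- paste0(base, "_volumes.csv")
  f2 <- paste0(base, "_changes.csv")
  f3 <- paste0(base, "_report.json")
  utils::write.csv(report$volumes, f1, row.names = FALSE)
  utils::write.csv(report$changes, f2, row.names = FALSE)
  jsonlite::write_json(
    list(subject_id = report$subject_id, audit = report$audit,
         volumes = report$volumes, changes = report$changes),
    f3, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(f1, f2, f3))
}

#' Cohort table from subject reports
#'
#' Collects each subject's last-measurement percent changes per
#' compartment into a cohort analysis table.
#'
#' @param reports List of `subject_report` objects.
#' @return Tibble with `subject_id`, `group`, and one
#'   `<compartment>_change` column per compartment.
#' @export
cohort_from_reports <- function(reports) {
  rows <- lapply(reports, function(rep) {
    stopifnot(inherits(rep, "subject_report"))
    ch <- dplyr::filter(rep$changes, .data$last)
    out <- tibble::tibble(subject_id = rep$subject_id,
                          group = rep$timeline$group)
    for (i in seq_len(nrow(ch)))
      out[[paste0(tolower(ch$compartment[i]), "_change")]] <- ch$change_pct[i]
    out
  })
  dplyr::bind_rows(rows)
}

#' Cohort-level summaries and tests
#'
#' Group means and SDs of a percent-change variable, one-way ANOVA across
#' groups with Bonferroni-corrected pairwise comparisons, and a per-group
#' Shapiro-Wilk normality check (groups failing it are flagged).
#'
#' @param data Cohort tibble (e.g. [load_cohort_table()] or
#'   [cohort_from_reports()]).
#' @param variable Variable column to analyze.
#' @param by Grouping column (default `"response"`).
#' @param therapies Optional therapy filter (e.g. [CIT_THERAPIES]).
#' @return Object of class `cohort_report` with `summary`, `anova`,
#'   `pairwise`, `normality`.
#' @export
run_cohort <- function(data, variable, by = "response", therapies = NULL) {
  summ <- group_summary(data, variable, by = by, therapies = therapies)
  if (!is.null(therapies))
    data <- dplyr::filter(data, .data$therapy %in% therapies)
  groups <- split(data[[variable]], data[[by]])
  groups <- groups[vapply(groups, length, integer(1)) >= 2L]
  anova <- if (length(groups) >= 2L) one_way_anova(groups) else NULL
  pairwise <- if (length(groups) >= 2L) pairwise_bonferroni(groups) else NULL
  normality <- dplyr::bind_rows(lapply(names(groups), function(g) {
    x <- groups[[g]]
    if (length(x) >= 3L && stats::sd(x) > 0) {
      sw <- shapiro_wilk(x)
      tibble::tibble(group = g, W = unname(sw$statistic), p = sw$p_value,
                     normal = sw$p_value >= SIGNIFICANCE_LEVEL)
    } else {
      tibble::tibble(group = g, W = NA_real_, p = NA_real_, normal = NA)
    }
  }))
  structure(list(variable = variable, by = by, therapies = therapies,
                 summary = summ, anova = anova, pairwise = pairwise,
                 normality = normality),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %s by %s%s\n", x$variable, x$by,
              if (!is.null(x$therapies))
                paste0(" (therapy: ", paste(x$therapies, collapse = ", "), ")")
              else ""))
  print(x$summary)
  if (!is.null(x$anova))
    cat(sprintf("ANOVA F = %.3f, p = %.4g\n",
                x$anova$statistic[["F"]], x$anova$p_value))
  invisible(x)
}

#' @export
print.subject_report <- function(x, ...) {
  cat(sprintf("<subject_report> %s (%d timepoints)\n", x$subject_id,
              length(unique(x$volumes$timepoint))))
  print(x$volumes)
  if (nrow(x$changes)) print(x$changes)
  invisible(x)
}
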