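#' Compartment volumes of a label volume
#'
#' Volume = voxel count x (row spacing x col spacing x slice thickness),
#' in mm^3 (1 mm^3 = 1 microlitre); excluded voxels are counted
#' separately. Mouse-scale results are conventionally reported in
#' microlitres, human-scale in millilitres (`volume_ml`).
#'
#' @param compartments A `body_compartments`, or an integer label array
#'   (then `spacing` must be given).
#' @param spacing Voxel spacing in mm `(row, col, slice)`; taken from the
#'   object when available.
#' @return Tibble with `compartment`, `voxels`, `volume_mm3`, `volume_ul`,
#'   `volume_ml`.
#' @export
compartment_volumes <- function(compartments, spacing = NULL) {
  if (inherits(compartments, "body_compartments")) {
    labels <- compartments$labels
    spacing <- compartments$spacing
  } else {
    labels <- compartments
    if (is.null(spacing)) stop("spacing is required for a bare label array")
  }
  stopifnot(length(spacing) == 3L, all(spacing > 0))
  vv <- prod(spacing)
  counts <- vapply(COMPARTMENT[-1], function(k) sum(labels == k), integer(1))
  tibble::tibble(
    compartment = names(COMPARTMENT)[-1],
    voxels = as.integer(counts),
    volume_mm3 = as.numeric(counts) * vv,
    volume_ul = as.numeric(counts) * vv,
    volume_ml = as.numeric(counts) * vv / 1000)
}

#' Caudocranial compartment profile
#'
#' Per-slice compartment volumes ordered caudal to cranial (slice index 1
#' = most caudal); the profile sums exactly to the total compartment
#' volumes.
#'
#' @param compartments A `body_compartments`.
#' @param reverse If `TRUE`, return the series cranial to caudal.
#' @return Tibble of class `axial_profile` with `slice`, `compartment`,
#'   `voxels`, `volume_mm3`.
#' @export
axial_profile <- function(compartments, reverse = FALSE) {
  stopifnot(inherits(compartments, "body_compartments"))
  vv <- prod(compartments$spacing)
  d <- dim(compartments$labels)
  rows <- lapply(seq_len(d[1]), function(s) {
    sl <- compartments$labels[s, , ]
    counts <- vapply(COMPARTMENT[-1], function(k) sum(sl == k), integer(1))
    tibble::tibble(slice = s, compartment = names(COMPARTMENT)[-1],
                   voxels = as.integer(counts),
                   volume_mm3 = as.numeric(counts) * vv)
  })
  out <- dplyr::bind_rows(rows)
  if (reverse)
    out <- dplyr::arrange(out, dplyr::desc(.data$slice), .data$compartment)
  class(out) <- c("axial_profile", class(out))
  out
}

#' Percent change from baseline
#'
#' `100 * (followup - baseline) / baseline`, signed. Follow-up
#' measurements are expressed this way to correct for individual baseline
#' values.
#'
#' @param baseline Baseline value(s), must be > 0.
#' @param followup Follow-up value(s).
#' @return Signed percent change (unrounded).
#' @export
percent_change <- function(baseline, followup) {
  if (any(baseline <= 0))
    stop("percent change undefined for baseline <= 0")
  100 * (followup - baseline) / baseline
}

#' Format a percent change at reporting precision
#'
#' Narrative convention: integer percent for volumes of a litre or more,
#' one decimal otherwise (e.g. body weights). Raw unrounded values should
#' always be retained alongside.
#'
#' @param pct Percent change value(s).
#' @param digits Decimal places; default chosen by `large_quantity`.
#' @param large_quantity If `TRUE` (litre-scale volumes) round to integer
#'   percent.
#' @return Character vector like `"-26%"` or `"-7.2%"`.
#' @export
format_percent <- function(pct, large_quantity = TRUE,
                           digits = if (large_quantity) 0L else 1L) {
  val <- round(pct, digits)
  sprintf(paste0("%+.", digits, "f%%"), val)
}

#' Total fat volume
#'
#' VAT + SCAT, in the units of the input.
#'
#' @param vat,scat Volumes (same units); or pass a `compartment_volumes`
#'   tibble as `vat` and leave `scat` missing.
#' @return Total fat volume.
#' @export
total_fat <- function(vat, scat = NULL) {
  if (is.data.frame(vat) && is.null(scat)) {
    tb <- vat
    vat <- tb$volume_mm3[tb$compartment == "VAT"]
    scat <- tb$volume_mm3[tb$compartment == "SCAT"]
  }
  stopifnot(is.numeric(vat), is.numeric(scat))
  vat + scat
}

#' Assemble a subject timeline
#'
#' @param subject_id Identifier.
#' @param species `"mouse"` or `"human"`.
#' @param timepoints Tibble with one row per timepoint: a `timepoint`
#'   label column plus compartment volume columns (`SCAT`, `VAT`, `LTW`,
#'   optionally `excluded`, mm^3) and optional `body_weight`, `bmi`.
#' @param group Optional free-text group/therapy/response label.
#' @return Object of class `subject_timeline`.
#' @export
subject_timeline <- function(subject_id, species = c("mouse", "human"),
                             timepoints, group = NA_character_) {
  species <- match.arg(species)
  stopifnot(is.data.frame(timepoints), nrow(timepoints) >= 1,
            "timepoint" %in% names(timepoints))
  if (anyDuplicated(timepoints$timepoint))
    stop("duplicate timepoint labels")
  vols <- intersect(c("SCAT", "VAT", "LTW"), names(timepoints))
  if (length(vols) == 0L) stop("no compartment volume columns found")
  for (v in vols) {
    if (any(timepoints[[v]] < 0, na.rm = TRUE))
      stop("volumes must be >= 0")
  }
  structure(list(subject_id = subject_id, species = species,
                 group = group,
                 timepoints = tibble::as_tibble(timepoints)),
            class = "subject_timeline")
}

#' Percent-change table across subjects
#'
#' For each subject and compartment, the percent change from baseline (the
#' first timepoint) at every follow-up; the change at the last measurement
#' is flagged with `last = TRUE`. Subjects lacking a compartment (zero or
#' missing baseline) are flagged via `undefined = TRUE`, not dropped.
#'
#' @param timelines A `subject_timeline` or list of them.
#' @return Tibble with `subject_id`, `group`, `compartment`, `timepoint`,
#'   `baseline`, `followup`, `change_pct`, `undefined`, `last`.
#' @export
build_change_table <- function(timelines) {
  if (inherits(timelines, "subject_timeline")) timelines <- list(timelines)
  rows <- lapply(timelines, function(tl) {
    stopifnot(inherits(tl, "subject_timeline"))
    tp <- tl$timepoints
    if (nrow(tp) < 2L)
      stop("subject ", tl$subject_id, " needs at least 2 timepoints")
    vols <- intersect(c("SCAT", "VAT", "LTW", "total_fat"), names(tp))
    out <- lapply(vols, function(v) {
      base <- tp[[v]][1]
      fup <- tp[[v]][-1]
      undef <- is.na(base) || base <= 0
      tibble::tibble(
        subject_id = tl$subject_id, group = tl$group, compartment = v,
        timepoint = tp$timepoint[-1],
        baseline = base, followup = fup,
        change_pct = if (undef) NA_real_ else percent_change(base, fup),
        undefined = undef,
        last = seq_along(fup) == length(fup))
    })
    dplyr::bind_rows(out)
  })
  dplyr::bind_rows(rows)
}
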