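#' Body mask of a single slice
#'
#' Otsu threshold on the total-signal image (W + F), morphological closing
#' (disk), hole filling, and removal of connected components below
#' `min_area` voxels. Remaining components are relabeled in decreasing
#' area order (so label 1 is the trunk in multi-part slices such as human
#' legs), which keeps downstream processing deterministic.
#'
#' @param slice_total 2D total-signal magnitude image.
#' @param min_area Minimum component area (voxels) to retain.
#' @param close_radius Radius of the closing disk.
#' @return Integer matrix of component labels (0 background); attribute
#'   `n_components`.
#' @export
body_mask <- function(slice_total, min_area = 64L, close_radius = 2L) {
  stopifnot(is.matrix(slice_total))
  out <- matrix(0L, nrow(slice_total), ncol(slice_total))
  mx <- max(slice_total)
  if (mx <= 0) {
    attr(out, "n_components") <- 0L
    return(out)
  }
  img <- slice_total / mx
  th <- EBImage::otsu(EBImage::Image(img))
  bw <- img > th
  brush <- EBImage::makeBrush(2L * close_radius + 1L, shape = "disc")
  bw <- EBImage::closing(bw, brush)
  bw <- EBImage::fillHull(bw)
  lab <- EBImage::bwlabel(bw)
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_area)
  if (length(keep) == 0L) {
    attr(out, "n_components") <- 0L
    return(out)
  }
  keep <- keep[order(areas[keep], decreasing = TRUE)]
  for (i in seq_along(keep)) out[lab == keep[i]] <- i
  attr(out, "n_components") <- length(keep)
  out
}

# voxels (0-based centres) inside a closed polygon; both in (row, col)
.inside_polygon <- function(poly, rows0, cols0) {
  bnd <- rbind(unclass(poly)[, 1:2], unclass(poly)[1, 1:2])
  mgcv::in.out(bnd, cbind(rows0, cols0))
}

#' Label compartments of one body component
#'
#' Given the fat-fraction slice, a body component mask, and the converged
#' inner (deep-fascia) contour: fat voxels (`FF >= ff_threshold`) between
#' the outer boundary and the inner contour are SCAT (1); fat voxels
#' strictly inside the inner contour are VAT (2); water-dominant voxels
#' inside the body are LTW (3); exclusion-mask voxels are labeled 4 and
#' removed from every compartment. A degenerate inner contour (area below
#' one voxel) labels all in-body fat as SCAT.
#'
#' @param ff_slice 2D fat-fraction image.
#' @param component Logical matrix: the body component to label.
#' @param inner A `snake_contour`, or `NULL`/degenerate.
#' @param exclusion Optional logical matrix of voxels to exclude.
#' @param ff_threshold Adipose classification threshold on FF.
#' @return Integer label matrix (codes 0-4) covering this component.
#' @export
label_compartments <- function(ff_slice, component, inner,
                               exclusion = NULL, ff_threshold = 0.5) {
  stopifnot(is.matrix(ff_slice), all(dim(ff_slice) == dim(component)))
  labels <- matrix(0L, nrow(ff_slice), ncol(ff_slice))
  idx <- which(component)
  if (length(idx) == 0L) return(labels)
  rc <- arrayInd(idx, dim(component))
  fat <- ff_slice[idx] >= ff_threshold
  degenerate <- is.null(inner) || abs(.poly_area(unclass(inner))) < 1
  if (degenerate) {
    if (!is.null(inner))
      message("degenerate inner contour; labeling all in-body fat as SCAT")
    inside <- rep(FALSE, length(idx))
  } else {
    inside <- .inside_polygon(inner, rc[, 1] - 1, rc[, 2] - 1)
  }
  lab <- ifelse(fat & inside, COMPARTMENT[["VAT"]],
                ifelse(fat, COMPARTMENT[["SCAT"]], COMPARTMENT[["LTW"]]))
  labels[idx] <- lab
  if (!is.null(exclusion)) {
    stopifnot(all(dim(exclusion) == dim(component)))
    labels[component & exclusion] <- COMPARTMENT[["excluded"]]
  }
  labels
}

#' Segment a decomposed volume into body compartments
#'
#' Per-slice, per-component pipeline: body masking on W + F, outer skin
#' contour extraction, inward snake propagation on the fat image, and
#' compartment labelling on the fat-fraction map, restricted to
#' `slice_range`. Failures on a slice are logged and that slice's in-body
#' voxels marked excluded rather than aborting the volume.
#'
#' @param fw A `fat_water_result`.
#' @param params A [snake_params()].
#' @param exclusions Optional logical array (same shape as the volume) of
#'   voxels to exclude (e.g. a tumor or prosthesis region).
#' @param slice_range Integer vector of slice indices to analyze
#'   (default: all).
#' @param ff_threshold Adipose classification threshold on FF.
#' @param min_area,close_radius Passed to [body_mask()].
#' @return An object of class `body_compartments`: `labels` (integer
#'   array, codes 0 background / 1 SCAT / 2 VAT / 3 LTW / 4 excluded),
#'   `spacing` (mm), `slice_range`, and a per-slice `log` tibble.
#' @export
segment_volume <- function(fw, params = snake_params(), exclusions = NULL,
                           slice_range = NULL, ff_threshold = 0.5,
                           min_area = 64L, close_radius = 2L) {
  stopifnot(inherits(fw, "fat_water_result"))
  d <- dim(fw$W)
  if (is.null(slice_range)) slice_range <- seq_len(d[1])
  stopifnot(all(slice_range >= 1L), all(slice_range <= d[1]))
  if (!is.null(exclusions)) stopifnot(all(dim(exclusions) == d))
  labels <- array(0L, dim = d)
  log <- list()
  for (s in slice_range) {
    total <- fw$W[s, , ] + fw$F[s, , ]
    comp_labels <- body_mask(total, min_area = min_area,
                             close_radius = close_radius)
    ncomp <- attr(comp_labels, "n_components")
    if (ncomp == 0L) {
      log[[length(log) + 1L]] <- tibble::tibble(
        slice = s, component = NA_integer_, converged = NA,
        iterations = NA_integer_, note = "empty slice, skipped")
      next
    }
    excl <- if (!is.null(exclusions)) exclusions[s, , ] else NULL
    slice_lab <- matrix(0L, d[2], d[3])
    for (ci in seq_len(ncomp)) {
      comp <- comp_labels == ci
      res <- tryCatch({
        init <- outer_contour(comp, params$n_vertices,
                              slice = s, component = ci)
        snk <- evolve_snake(init, fw$F[s, , ], params, body_mask = comp)
        inner <- if (isTRUE(attr(snk, "collapsed"))) NULL else snk
        lab <- label_compartments(fw$FF[s, , ], comp, inner,
                                  exclusion = excl,
                                  ff_threshold = ff_threshold)
        list(lab = lab, converged = isTRUE(attr(snk, "converged")),
             iterations = attr(snk, "iterations"), note = "")
      }, error = function(e) {
        lab <- matrix(0L, d[2], d[3])
        lab[comp] <- COMPARTMENT[["excluded"]]
        list(lab = lab, converged = FALSE, iterations = NA_integer_,
             note = paste("failed:", conditionMessage(e)))
      })
      slice_lab[res$lab > 0L] <- res$lab[res$lab > 0L]
      log[[length(log) + 1L]] <- tibble::tibble(
        slice = s, component = ci, converged = res$converged,
        iterations = res$iterations, note = res$note)
    }
    labels[s, , ] <- slice_lab
  }
  spacing <- c(fw$protocol$in_plane_spacing, fw$protocol$slice_thickness)
  structure(
    list(labels = labels, spacing = spacing,
         slice_range = as.integer(slice_range),
         log = dplyr::bind_rows(log),
         audit = list()),
    class = "body_compartments")
}

#' Manually override segmentation labels
#'
#' Reassigns every voxel of a correction mask to `new_label`, recording an
#' audit entry (voxel count changed, timestamp). This is the hook for the
#' visual-validation corrections of the automated segmentation, including
#' excluding an artifact region (label 4) consistently across timepoints.
#'
#' @param compartments A `body_compartments`.
#' @param correction Logical array matching the label volume.
#' @param new_label Integer label code in 0-4.
#' @return The modified `body_compartments` (audit appended).
#' @export
apply_manual_override <- function(compartments, correction, new_label) {
  stopifnot(inherits(compartments, "body_compartments"))
  if (!(new_label %in% COMPARTMENT))
    stop("invalid label code: ", new_label, " (must be one of 0-4)")
  stopifnot(all(dim(correction) == dim(compartments$labels)))
  correction <- correction & TRUE
  changed <- sum(compartments$labels[correction] != as.integer(new_label))
  compartments$labels[correction] <- as.integer(new_label)
  compartments$audit <- c(compartments$audit,
                          list(list(voxels_changed = changed,
                                    new_label = as.integer(new_label),
                                    timestamp = format(Sys.time()))))
  compartments
}

#' @export
print.body_compartments <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<body_compartments> %d slices x %d x %d (%d analyzed)\n",
              d[1], d[2], d[3], length(x$slice_range)))
  print(compartment_volumes(x))
  invisible(x)
}
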