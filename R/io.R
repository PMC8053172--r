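#' Write a simulated dataset to disk
#'
#' Emits NIfTI volumes for the echo series (real and imaginary channels as
#' separate 4D volumes, or a single magnitude volume), ground-truth masks
#' when an anatomy is supplied, and a JSON sidecar recording the protocol
#' and seed. Arrays round-trip exactly through [read_dataset()].
#'
#' @param series An `echo_series`.
#' @param anatomy Optional `labeled_anatomy`; its compartment labels and
#'   tissue labels are written as NIfTI.
#' @param path Existing directory to write into.
#' @param name Basename prefix for all files.
#' @return Invisibly, the named character vector of files written.
#' @export
write_dataset <- function(series, anatomy = NULL, path, name = "phantom") {
  stopifnot(inherits(series, "echo_series"))
  if (!dir.exists(path))
    stop("output directory does not exist: ", path)
  pr <- series$protocol
  files <- c()
  wr <- function(arr, suffix) {
    f <- file.path(path, paste0(name, "_", suffix, ".nii"))
    RNifti::writeNifti(arr, f, datatype = "double")
    files[[suffix]] <<- f
    f
  }
  if (series$magnitude_only) {
    wr(series$data, "mag")
  } else {
    wr(Re(series$data), "real")
    wr(Im(series$data), "imag")
  }
  if (!is.null(anatomy)) {
    wr(anatomy$compartments, "compartments")
    wr(anatomy$tissue, "tissue")
    wr(anatomy$water, "water")
    wr(anatomy$fat, "fat")
  }
  sidecar <- list(field_strength_T = pr$field_strength,
                  echo_times_ms = pr$echo_times,
                  spacing_mm = c(pr$in_plane_spacing, pr$slice_thickness),
                  matrix = pr$matrix_size,
                  seed = series$seed,
                  shift_ppm = pr$fat_water_shift,
                  magnitude_only = series$magnitude_only)
  sidecar_path <- file.path(path, paste0(name, ".json"))
  jsonlite::write_json(sidecar, sidecar_path, auto_unbox = TRUE, digits = NA)
  files[["sidecar"]] <- sidecar_path
  invisible(unlist(files))
}

#' Read a dataset written by [write_dataset()]
#'
#' @param path Directory containing the files.
#' @param name Basename prefix used at write time.
#' @return A list with `series` (an `echo_series`), `sidecar` (the parsed
#'   JSON), and, when present, `compartments`, `tissue`, `water`, `fat`.
#' @export
read_dataset <- function(path, name = "phantom") {
  sidecar_path <- file.path(path, paste0(name, ".json"))
  if (!file.exists(sidecar_path))
    stop("no dataset sidecar found at: ", sidecar_path)
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  protocol <- acquisition_protocol(
    field_strength = sc$field_strength_T,
    echo_times = sc$echo_times_ms,
    in_plane_spacing = sc$spacing_mm[1:2],
    slice_thickness = sc$spacing_mm[3],
    matrix_size = sc$matrix,
    fat_water_shift = sc$shift_ppm)
  rd <- function(suffix) {
    f <- file.path(path, paste0(name, "_", suffix, ".nii"))
    if (!file.exists(f)) return(NULL)
    a <- RNifti::readNifti(f)
    array(as.numeric(a), dim = dim(a))
  }
  data <- if (isTRUE(sc$magnitude_only)) {
    rd("mag")
  } else {
    re <- rd("real"); im <- rd("imag")
    array(complex(real = re, imaginary = im), dim = dim(re))
  }
  series <- structure(
    list(data = data, protocol = protocol,
         magnitude_only = isTRUE(sc$magnitude_only),
         truth = NULL, seed = sc$seed),
    class = "echo_series")
  out <- list(series = series, sidecar = sc)
  for (suffix in c("compartments", "tissue", "water", "fat")) {
    a <- rd(suffix)
    if (!is.null(a)) out[[suffix]] <- a
  }
  out
}
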