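#' Specify a digital body phantom
#'
#' Describes a simple layered anatomy used to exercise the whole pipeline
#' with analytic ground truth: an elliptical body cross-section with (from
#' the outside in) a thin skin layer, a closed subcutaneous-fat (SCAT)
#' annulus, a muscle/fascia layer, and a visceral cavity containing
#' water-dominant organ tissue plus a set of circular visceral-fat (VAT)
#' blobs that run through all slices. An optional subcutaneous tumor can be
#' attached to the SCAT ring.
#'
#' @param preset `"mouse"` or `"human"`; sets the protocol and mm-scale
#'   geometry defaults. All defaults can be overridden.
#' @param protocol An [acquisition_protocol()]; defaults to the preset's.
#' @param n_slices Number of axial slices (slice index 1 = most caudal).
#' @param semi_axes Body-outline ellipse semi-axes in mm, `(row, col)`.
#' @param scat_thickness SCAT annulus thickness in mm.
#' @param skin_thickness Skin layer thickness in mm.
#' @param muscle_thickness Muscle/fascia layer thickness in mm.
#' @param vat_n Number of VAT blobs (0 for none).
#' @param vat_radius_range Range of VAT blob radii in mm, length 2.
#' @param lean_ff Fat fraction of lean tissue (skin, muscle, organs), in
#'   `[0, 0.1]`.
#' @param adipose_ff Fat fraction of adipose tissue, in `[0.8, 1]`.
#' @param tumor `NULL` or `list(angle_deg=, radius=, ff=)` describing a
#'   subcutaneous tumor disk centred on the SCAT ring.
#' @param b0_amplitude Peak off-resonance of the smooth polynomial B0 map,
#'   in Hz.
#' @param noise_sd Complex-noise standard deviation as a fraction of the
#'   mean in-body signal magnitude (an SNR of 30 corresponds to 1/30).
#' @param seed Integer seed controlling blob placement and noise draws.
#'
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(preset = c("mouse", "human"),
                         protocol = NULL,
                         n_slices = NULL,
                         semi_axes = NULL,
                         scat_thickness = NULL,
                         skin_thickness = NULL,
                         muscle_thickness = NULL,
                         vat_n = 5L,
                         vat_radius_range = NULL,
                         lean_ff = 0.05,
                         adipose_ff = 0.9,
                         tumor = NULL,
                         b0_amplitude = 0,
                         noise_sd = 0,
                         seed = 1L) {
  preset <- match.arg(preset)
  def <- switch(preset,
    mouse = list(protocol = protocol_preset("mouse7t"), n_slices = 10L,
                 semi_axes = c(11, 14), scat_thickness = 1.5,
                 skin_thickness = 0.5, muscle_thickness = 2,
                 vat_radius_range = c(1.5, 2.2)),
    human = list(protocol = protocol_preset("human3t"), n_slices = 8L,
                 semi_axes = c(110, 160), scat_thickness = 15,
                 skin_thickness = 2.6, muscle_thickness = 15,
                 vat_radius_range = c(15, 25)))
  protocol <- protocol %||% def$protocol
  n_slices <- as.integer(n_slices %||% def$n_slices)
  semi_axes <- as.numeric(semi_axes %||% def$semi_axes)
  scat_thickness <- scat_thickness %||% def$scat_thickness
  skin_thickness <- skin_thickness %||% def$skin_thickness
  muscle_thickness <- muscle_thickness %||% def$muscle_thickness
  vat_radius_range <- as.numeric(vat_radius_range %||% def$vat_radius_range)

  stopifnot(inherits(protocol, "acquisition_protocol"),
            n_slices >= 1L, length(semi_axes) == 2L, all(semi_axes > 0),
            scat_thickness > 0, skin_thickness > 0, muscle_thickness > 0,
            vat_n >= 0, length(vat_radius_range) == 2L,
            lean_ff >= 0, lean_ff <= 0.1,
            adipose_ff >= 0.8, adipose_ff <= 1)
  if (scat_thickness >= min(semi_axes))
    stop("phantom geometrically infeasible: scat_thickness (", scat_thickness,
         " mm) must be smaller than the smallest body semi-axis (",
         min(semi_axes), " mm)")
  if (skin_thickness + scat_thickness + muscle_thickness >= min(semi_axes))
    stop("phantom geometrically infeasible: layers thicker than the body")
  if (!is.null(tumor)) {
    stopifnot(is.list(tumor), !is.null(tumor$radius), tumor$radius > 0)
    tumor$angle_deg <- tumor$angle_deg %||% 45
    tumor$ff <- tumor$ff %||% 0.1
    stopifnot(tumor$ff >= 0, tumor$ff <= 1)
  }
  structure(
    list(preset = preset, protocol = protocol, n_slices = n_slices,
         semi_axes = semi_axes, scat_thickness = scat_thickness,
         skin_thickness = skin_thickness, muscle_thickness = muscle_thickness,
         vat_n = as.integer(vat_n), vat_radius_range = vat_radius_range,
         lean_ff = lean_ff, adipose_ff = adipose_ff, tumor = tumor,
         b0_amplitude = b0_amplitude, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "phantom_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run expr with a private RNG state seeded by `seed`; restores the caller's.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Continuum slice geometry for a spec, optionally with per-compartment scale
# factors applied (see make_longitudinal). Fascia ellipse is the base layer;
# outer layers are offset ellipses.
phantom_geometry <- function(spec, factors = c(scat = 1, vat = 1, ltw = 1)) {
  af0 <- spec$semi_axes[1] - spec$skin_thickness - spec$scat_thickness
  bf0 <- spec$semi_axes[2] - spec$skin_thickness - spec$scat_thickness
  blobs0 <- place_vat_blobs(spec, af0, bf0)
  t0 <- spec$scat_thickness
  kt <- spec$skin_thickness

  scat_area <- function(af, bf, t) pi * ((af + t) * (bf + t) - af * bf)
  skin_area <- function(af, bf, t)
    pi * ((af + t + kt) * (bf + t + kt) - (af + t) * (bf + t))
  vat_area0 <- if (nrow(blobs0)) sum(pi * blobs0$r^2) else 0

  S0 <- scat_area(af0, bf0, t0)
  LTW0 <- pi * af0 * bf0 - vat_area0 + skin_area(af0, bf0, t0)

  f <- factors
  vat_area_t <- vat_area0 * f[["vat"]]
  # SCAT thickness for a given fascia scale s, keeping SCAT area = f_scat*S0
  scat_t_for <- function(s) {
    P <- s * (af0 + bf0)
    (-P + sqrt(P^2 + 4 * f[["scat"]] * S0 / pi)) / 2
  }
  if (abs(f[["ltw"]] - 1) < 1e-12 && abs(f[["vat"]] - 1) < 1e-12 &&
      abs(f[["scat"]] - 1) < 1e-12) {
    s <- 1; tt <- t0
  } else {
    ltw_area <- function(s) {
      tt <- scat_t_for(s)
      pi * (af0 * s) * (bf0 * s) - vat_area_t + skin_area(af0 * s, bf0 * s, tt)
    }
    s <- stats::uniroot(function(s) ltw_area(s) - f[["ltw"]] * LTW0,
                        c(0.3, 2), tol = 1e-10)$root
    tt <- scat_t_for(s)
  }
  blobs <- blobs0
  if (nrow(blobs)) {
    blobs$cy <- blobs$cy * s
    blobs$cx <- blobs$cx * s
    blobs$r <- blobs$r * sqrt(f[["vat"]])
    if (any(blobs$r < max(spec$protocol$in_plane_spacing)))
      stop("infeasible shrink: a VAT blob falls below one voxel and vanishes")
  }
  if (tt < max(spec$protocol$in_plane_spacing) && f[["scat"]] > 0)
    stop("infeasible shrink: SCAT annulus falls below one voxel")
  list(fascia = c(af0 * s, bf0 * s), scat_t = tt, skin_t = kt,
       muscle_t = spec$muscle_thickness, blobs = blobs, tumor = spec$tumor)
}

# Deterministic non-overlapping blob placement inside the visceral cavity.
place_vat_blobs <- function(spec, af, bf) {
  n <- spec$vat_n
  empty <- data.frame(cy = numeric(0), cx = numeric(0), r = numeric(0))
  if (n == 0L) return(empty)
  acav <- af - spec$muscle_thickness
  bcav <- bf - spec$muscle_thickness
  if (min(acav, bcav) <= max(spec$vat_radius_range))
    stop("phantom geometrically infeasible: VAT blobs larger than the cavity")
  with_seed(spec$seed, {
    rs <- stats::runif(n, spec$vat_radius_range[1], spec$vat_radius_range[2])
    margin <- 0.2 * min(spec$vat_radius_range)
    cy <- cx <- numeric(0)
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in 1:4000) {
        u <- stats::runif(1, -1, 1); v <- stats::runif(1, -1, 1)
        y <- u * (acav - rs[i] - margin); x <- v * (bcav - rs[i] - margin)
        if ((y / (acav - rs[i] - margin))^2 +
            (x / (bcav - rs[i] - margin))^2 > 1) next
        if (i > 1 && any(sqrt((y - cy)^2 + (x - cx)^2) <
                         rs[i] + rs[seq_len(i - 1)] + margin)) next
        cy <- c(cy, y); cx <- c(cx, x); placed <- TRUE; break
      }
      if (!placed) stop("could not place VAT blob ", i,
                        "; reduce vat_n or blob radii")
    }
    data.frame(cy = cy, cx = cx, r = rs)
  })
}

# tissue codes
TISSUE <- c(background = 0L, skin = 1L, scat = 2L, muscle = 3L,
            organ = 4L, vat = 5L, tumor = 6L)
# compartment codes (label volume vocabulary used throughout)
COMPARTMENT <- c(background = 0L, SCAT = 1L, VAT = 2L, LTW = 3L,
                 excluded = 4L)

#' Build a labeled digital anatomy
#'
#' Rasterizes a [phantom_spec()] onto the protocol's voxel grid: every voxel
#' centre is classified into a tissue (skin, SCAT, muscle, organ, VAT blob,
#' tumor), and ground-truth water/fat density maps plus a compartment label
#' volume (`0` background, `1` SCAT, `2` VAT, `3` LTW, `4` excluded) are
#' derived deterministically from the tissue labels. Water + fat density is
#' 1 inside the body, 0 outside.
#'
#' @param spec A [phantom_spec()].
#' @param factors Internal: per-compartment continuum scale factors
#'   (named `scat`, `vat`, `ltw`), used by [make_longitudinal()].
#' @return An object of class `labeled_anatomy` with elements `tissue`,
#'   `water`, `fat`, `compartments` (arrays of dim slices x rows x cols),
#'   `spacing` (mm, `(row, col, slice)`), `geometry` and `spec`.
#' @export
build_phantom <- function(spec, factors = c(scat = 1, vat = 1, ltw = 1)) {
  stopifnot(inherits(spec, "phantom_spec"))
  geo <- phantom_geometry(spec, factors)
  pr <- spec$protocol
  nr <- pr$matrix_size[1]; nc <- pr$matrix_size[2]; ns <- spec$n_slices
  dy <- pr$in_plane_spacing[1]; dx <- pr$in_plane_spacing[2]

  y <- (seq_len(nr) - (nr + 1) / 2) * dy
  x <- (seq_len(nc) - (nc + 1) / 2) * dx
  Y <- matrix(y, nr, nc)
  X <- matrix(x, nr, nc, byrow = TRUE)

  inside <- function(ay, ax) (Y / ay)^2 + (X / ax)^2 <= 1
  af <- geo$fascia[1]; bf <- geo$fascia[2]
  body <- inside(af + geo$scat_t + geo$skin_t, bf + geo$scat_t + geo$skin_t)
  scat_out <- inside(af + geo$scat_t, bf + geo$scat_t)
  fascia <- inside(af, bf)
  cavity <- inside(af - geo$muscle_t, bf - geo$muscle_t)

  tis <- matrix(TISSUE[["background"]], nr, nc)
  tis[body] <- TISSUE[["skin"]]
  tis[scat_out] <- TISSUE[["scat"]]
  tis[fascia] <- TISSUE[["muscle"]]
  tis[cavity] <- TISSUE[["organ"]]
  if (nrow(geo$blobs)) {
    for (i in seq_len(nrow(geo$blobs))) {
      b <- geo$blobs[i, ]
      inblob <- cavity & ((Y - b$cy)^2 + (X - b$cx)^2 <= b$r^2)
      tis[inblob] <- TISSUE[["vat"]]
    }
  }
  if (!is.null(geo$tumor)) {
    th <- geo$tumor$angle_deg * pi / 180
    rmid <- c((af + geo$scat_t / 2) * sin(th), (bf + geo$scat_t / 2) * cos(th))
    intum <- body & ((Y - rmid[1])^2 + (X - rmid[2])^2 <= geo$tumor$radius^2)
    tis[intum] <- TISSUE[["tumor"]]
  }

  tissue <- array(0L, dim = c(ns, nr, nc))
  for (s in seq_len(ns)) tissue[s, , ] <- tis

  ff_of <- c(NA, spec$lean_ff, spec$adipose_ff, spec$lean_ff, spec$lean_ff,
             spec$adipose_ff,
             if (!is.null(geo$tumor)) geo$tumor$ff else NA)
  ff <- array(0, dim = dim(tissue))
  for (code in 1:6) {
    if (is.na(ff_of[code + 1])) next
    ff[tissue == code] <- ff_of[code + 1]
  }
  water <- array(0, dim = dim(tissue))
  fat <- array(0, dim = dim(tissue))
  inb <- tissue > 0L
  water[inb] <- 1 - ff[inb]
  fat[inb] <- ff[inb]

  comp_of <- c(0L, COMPARTMENT[["LTW"]], COMPARTMENT[["SCAT"]],
               COMPARTMENT[["LTW"]], COMPARTMENT[["LTW"]],
               COMPARTMENT[["VAT"]], COMPARTMENT[["excluded"]])
  compartments <- array(comp_of[tissue + 1L], dim = dim(tissue))

  structure(
    list(tissue = tissue, water = water, fat = fat,
         compartments = compartments,
         spacing = c(dy, dx, pr$slice_thickness),
         geometry = geo, spec = spec),
    class = "labeled_anatomy")
}

#' Ground-truth compartment volumes of an anatomy
#'
#' @param anatomy A `labeled_anatomy`.
#' @return A tibble with columns `compartment`, `voxels`, `volume_mm3`.
#' @export
true_volumes <- function(anatomy) {
  stopifnot(inherits(anatomy, "labeled_anatomy"))
  vv <- prod(anatomy$spacing)
  comp <- anatomy$compartments
  tibble::tibble(
    compartment = names(COMPARTMENT)[-1],
    voxels = vapply(COMPARTMENT[-1], function(k) sum(comp == k), integer(1)),
    volume_mm3 = .data_voxels_to_mm3(vapply(COMPARTMENT[-1],
                                            function(k) sum(comp == k),
                                            integer(1)), vv))
}

.data_voxels_to_mm3 <- function(n, vv) as.numeric(n) * vv

#' Generate a longitudinal phantom series
#'
#' Builds one anatomy and simulated echo series per timepoint, with
#' prescribed per-compartment volume trajectories (multiplicative factors
#' relative to baseline; first timepoint must be 1). VAT scaling acts on
#' blob radii, SCAT on annulus thickness, LTW on the fascia ellipse; the
#' continuum geometry is solved so that each prescribed factor is exact up
#' to rasterization, emulating a three-timepoint monitoring design.
#'
#' @param spec A [phantom_spec()] describing the baseline.
#' @param trajectory Named list of numeric factor vectors (any of `vat`,
#'   `scat`, `ltw`), all the same length (= number of timepoints), each
#'   starting at 1 and strictly positive.
#' @param simulate If `TRUE`, also simulate an echo series per timepoint.
#' @return List of timepoints, each `list(anatomy=, series=)` (`series`
#'   `NULL` when `simulate = FALSE`).
#' @export
make_longitudinal <- function(spec, trajectory, simulate = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"), is.list(trajectory),
            length(trajectory) >= 1)
  bad <- setdiff(names(trajectory), c("vat", "scat", "ltw"))
  if (length(bad)) stop("unknown trajectory compartments: ",
                        paste(bad, collapse = ", "))
  nt <- unique(vapply(trajectory, length, integer(1)))
  if (length(nt) != 1L) stop("trajectory vectors must have equal length")
  for (nm in names(trajectory)) {
    f <- trajectory[[nm]]
    if (any(f <= 0)) stop("trajectory factors must be > 0")
    if (abs(f[1] - 1) > 1e-12)
      stop("first timepoint factor must be 1 (baseline)")
  }
  lapply(seq_len(nt), function(t) {
    fac <- c(scat = 1, vat = 1, ltw = 1)
    for (nm in names(trajectory)) fac[[nm]] <- trajectory[[nm]][t]
    anatomy <- build_phantom(spec, factors = fac)
    series <- if (simulate)
      simulate_echoes(anatomy, spec$protocol,
                      b0_amplitude = spec$b0_amplitude,
                      noise_sd = spec$noise_sd,
                      seed = spec$seed + 7919L * t)
    else NULL
    list(anatomy = anatomy, series = series)
  })
}

#' @export
print.labeled_anatomy <- function(x, ...) {
  d <- dim(x$tissue)
  cat(sprintf("<labeled_anatomy> %d slices x %d x %d, spacing %.3f x %.3f x %.2f mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  print(true_volumes(x))
  invisible(x)
}
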