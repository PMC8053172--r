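#' Smooth polynomial B0 map
#'
#' A fixed-shape low-order 2D polynomial per slice, scaled so that its peak
#' magnitude inside the body equals `amplitude` Hz; a small linear term in
#' the slice index makes the field vary smoothly along the body axis.
#' Smooth fields of this kind are the regime Dixon off-resonance resolution
#' assumes.
#'
#' @param anatomy A `labeled_anatomy` (defines dims and the body mask).
#' @param amplitude Peak |off-resonance| in Hz (0 gives a zero field).
#' @return Array of off-resonance values (Hz), dim slices x rows x cols.
#' @export
b0_field <- function(anatomy, amplitude) {
  d <- dim(anatomy$tissue)
  psi <- array(0, dim = d)
  if (amplitude == 0) return(psi)
  nr <- d[2]; nc <- d[3]
  u <- matrix(seq(-1, 1, length.out = nr), nr, nc)
  v <- matrix(seq(-1, 1, length.out = nc), nr, nc, byrow = TRUE)
  base <- 0.35 + 0.45 * u + 0.35 * v + 0.25 * u^2 - 0.2 * u * v - 0.15 * v^2
  body <- anatomy$tissue > 0L
  for (s in seq_len(d[1])) {
    tilt <- if (d[1] > 1) 0.1 * (s - 1) / (d[1] - 1) else 0
    f <- base + tilt
    m <- max(abs(f[body[s, , ]]))
    if (m == 0) m <- max(abs(f))
    psi[s, , ] <- f / m * amplitude
  }
  psi
}

#' Simulate a multi-echo Dixon acquisition
#'
#' Applies the single-peak chemical-shift signal model per voxel:
#' \deqn{s_k = (W + F e^{i 2\pi \Delta f TE_k}) e^{i(\phi_0 + 2\pi \psi TE_k)} + n_k}
#' with \eqn{\Delta f} the fat-water frequency offset of the protocol,
#' \eqn{\psi} the local B0 off-resonance in Hz, and \eqn{n_k} complex
#' Gaussian noise applied independently on the real and imaginary channels.
#' The noise standard deviation is `noise_sd` times the mean in-body
#' noise-free signal magnitude.
#'
#' @param anatomy A `labeled_anatomy` supplying ground-truth W and F maps.
#' @param protocol An [acquisition_protocol()]; must match the anatomy grid.
#' @param b0_amplitude Peak B0 inhomogeneity in Hz (see [b0_field()]).
#' @param noise_sd Noise level as a fraction of mean in-body signal.
#' @param seed Integer seed for the noise draw.
#' @param phi0 Constant initial phase in radians.
#' @param magnitude_only If `TRUE`, export voxel magnitudes (Rician
#'   statistics arise naturally from the complex noise).
#' @return An object of class `echo_series`: `data` (complex, or double if
#'   magnitude-only; dim slices x rows x cols x echoes), `protocol`,
#'   `magnitude_only`, and `truth` (the `psi` field and `phi0` used).
#' @export
simulate_echoes <- function(anatomy, protocol = anatomy$spec$protocol,
                            b0_amplitude = 0, noise_sd = 0, seed = 1L,
                            phi0 = 0, magnitude_only = FALSE) {
  stopifnot(inherits(anatomy, "labeled_anatomy"),
            inherits(protocol, "acquisition_protocol"))
  d <- dim(anatomy$water)
  if (!all(d[2:3] == protocol$matrix_size))
    stop("anatomy grid ", d[2], "x", d[3],
         " does not match protocol matrix ",
         paste(protocol$matrix_size, collapse = "x"))
  te <- protocol$echo_times / 1000           # seconds
  dfz <- fat_water_offset(protocol)          # Hz
  psi <- b0_field(anatomy, b0_amplitude)
  K <- length(te)
  data <- array(complex(real = 0), dim = c(d, K))
  for (k in seq_len(K)) {
    fatph <- exp(1i * 2 * pi * dfz * te[k])
    data[, , , k] <- (anatomy$water + anatomy$fat * fatph) *
      exp(1i * (phi0 + 2 * pi * psi * te[k]))
  }
  if (noise_sd > 0) {
    body <- anatomy$tissue > 0L
    mean_sig <- mean(abs(data[array(body, dim = c(d, K))]))
    sd_abs <- noise_sd * mean_sig
    n <- length(data)
    with_seed(seed, {
      data <- data + complex(real = stats::rnorm(n, 0, sd_abs),
                             imaginary = stats::rnorm(n, 0, sd_abs))
    })
  }
  if (magnitude_only) data <- abs(data)
  structure(
    list(data = data, protocol = protocol, magnitude_only = magnitude_only,
         truth = list(psi = psi, phi0 = phi0), seed = as.integer(seed)),
    class = "echo_series")
}

#' @export
print.echo_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<echo_series> %d slices x %d x %d, %d echoes (%s)\n",
              d[1], d[2], d[3], d[4],
              if (x$magnitude_only) "magnitude" else "complex"))
  invisible(x)
}
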