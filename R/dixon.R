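# Vectorized non-negative water/fat amplitude fit at a given off-resonance.
#
# For demodulated signals d_k = s_k exp(-i 2 pi psi TE_k) the model is
# d_k = W + F c_k with c_k = exp(i 2 pi dfz TE_k) and real W, F >= 0.
# Stacking real/imaginary parts gives a 2x2 normal-equation system whose
# matrix depends only on the echo times (|c_k| = 1 so both diagonal entries
# equal K); negativity is handled by clamping to the active-set solution.
#
# S: n x K complex matrix; te in seconds; psi scalar or length n (Hz).
.fw_fit <- function(S, te, dfz, psi) {
  K <- length(te)
  cph <- exp(1i * 2 * pi * dfz * te)
  psi <- as.numeric(psi)
  if (length(psi) == 1L) psi <- rep(psi, nrow(S))
  D <- S * exp(-1i * 2 * pi * outer(psi, te))
  m12 <- sum(Re(cph))
  v1 <- rowSums(Re(D))
  v2 <- Re(D %*% Conj(cph))[, 1]
  det <- K * K - m12 * m12
  W <- (K * v1 - m12 * v2) / det
  F_ <- (K * v2 - m12 * v1) / det
  # active-set clamp for the non-negativity constraints
  negF <- F_ < 0
  if (any(negF)) {
    F_[negF] <- 0
    W[negF] <- pmax(v1[negF] / K, 0)
  }
  negW <- W < 0
  if (any(negW)) {
    W[negW] <- 0
    F_[negW] <- pmax(v2[negW] / K, 0)
  }
  ss <- rowSums(Mod(D)^2)
  resid <- ss - 2 * (W * v1 + F_ * v2) +
    W^2 * K + 2 * W * F_ * m12 + F_^2 * K
  list(W = W, F = F_, residual = pmax(resid, 0))
}

#' Residual profile of the chemical-shift model at a given off-resonance
#'
#' For one voxel (or a batch of voxels) evaluates
#' \deqn{R(\psi) = \min_{W,F \ge 0} \sum_k |s_k - (W + F e^{i2\pi\Delta f TE_k}) e^{i2\pi\psi TE_k}|^2}
#' returning the attained residual and the minimizing non-negative
#' amplitudes. This is the objective whose two local minima over one
#' aliasing period generate the fat/water swap ambiguity.
#'
#' @param signals Complex vector of length K (one voxel) or an n x K
#'   complex matrix (one row per voxel).
#' @param protocol An [acquisition_protocol()].
#' @param psi Off-resonance in Hz; scalar or length n.
#' @return A list with numeric vectors `residual`, `W`, `F`.
#' @export
residual_profile <- function(signals, protocol, psi) {
  stopifnot(inherits(protocol, "acquisition_protocol"))
  if (is.null(dim(signals))) signals <- matrix(signals, nrow = 1)
  if (ncol(signals) != length(protocol$echo_times))
    stop("signals must have one column per echo")
  fit <- .fw_fit(signals, protocol$echo_times / 1000,
                 fat_water_offset(protocol), psi)
  list(residual = fit$residual, W = fit$W, F = fit$F)
}

# Vectorized golden-section refinement of R(psi) local minima.
# lo/hi are per-voxel brackets (each containing one local minimum).
.golden_refine <- function(S, te, dfz, lo, hi, iters = 45L) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c_ <- b - gr * (b - a)
  d_ <- a + gr * (b - a)
  fc <- .fw_fit(S, te, dfz, c_)$residual
  fd <- .fw_fit(S, te, dfz, d_)$residual
  for (i in seq_len(iters)) {
    sel <- fc < fd
    b[sel] <- d_[sel]; d_[sel] <- c_[sel]; fd[sel] <- fc[sel]
    a[!sel] <- c_[!sel]; c_[!sel] <- d_[!sel]; fc[!sel] <- fd[!sel]
    c_new <- b - gr * (b - a)
    d_new <- a + gr * (b - a)
    x <- ifelse(sel, c_new, d_new)
    fx <- .fw_fit(S, te, dfz, x)$residual
    c_[sel] <- c_new[sel]; fc[sel] <- fx[sel]
    d_[!sel] <- d_new[!sel]; fd[!sel] <- fx[!sel]
  }
  mid <- (a + b) / 2
  fit <- .fw_fit(S, te, dfz, mid)
  list(psi = mid, residual = fit$residual, W = fit$W, F = fit$F)
}

#' Two-candidate off-resonance solutions per voxel (three-point Dixon)
#'
#' Locates, per in-mask voxel, the two lowest local minima of the residual
#' profile R(psi) over the search window `[-1/(2 dTE), +1/(2 dTE)]` (dTE
#' from the first echo pair): a coarse grid scan followed by
#' golden-section refinement. One candidate corresponds to the true field,
#' the other to the fat/water-swapped alias; candidates are ordered by
#' residual. Because the global phase is fixed, R is treated on the window
#' as an interval (endpoint minima are valid candidates).
#'
#' @param series An `echo_series` with exactly 3 complex echoes.
#' @param mask Logical array (slices x rows x cols); `NULL` uses every
#'   voxel with mean echo magnitude above 5% of the maximum.
#' @param n_grid Number of coarse grid points over the period.
#' @return An object of class `candidate_field`: arrays `psi1`, `psi2`
#'   (Hz), `r1`, `r2` (residuals), `W1`, `F1`, `W2`, `F2`, `magnitude`,
#'   logical `degenerate`, plus `mask`, `period` and the protocol.
#' @export
three_point_candidates <- function(series, mask = NULL, n_grid = 96L) {
  stopifnot(inherits(series, "echo_series"))
  if (series$magnitude_only)
    stop("three-point candidates require complex data")
  d <- dim(series$data)
  if (d[4] != 3L) stop("three-point decomposition requires exactly 3 echoes")
  te <- series$protocol$echo_times / 1000
  dfz <- fat_water_offset(series$protocol)
  dte <- te[2] - te[1]
  period <- 1 / dte
  mag <- apply(abs(series$data), 1:3, mean)
  if (is.null(mask)) mask <- mag > 0.05 * max(mag)
  stopifnot(all(dim(mask) == d[1:3]))
  if (!any(mask)) stop("mask is empty")

  idx <- which(mask)
  n <- length(idx)
  S <- matrix(complex(real = 0), n, 3)
  flat <- matrix(series$data, ncol = 3)
  S <- flat[idx, , drop = FALSE]

  # Note: with the global phase fixed, R(psi) is not exactly periodic in
  # 1/dTE (the echo times are not integer multiples of dTE), so the search
  # window is treated as an interval, not a circle: endpoint minima are
  # legitimate candidates and no wrap-around comparison is made.
  m <- n_grid + 1L
  grid <- seq(-period / 2, period / 2, length.out = m)
  Rg <- matrix(0, n, m)
  for (g in seq_len(m))
    Rg[, g] <- .fw_fit(S, te, dfz, grid[g])$residual

  is_min <- matrix(FALSE, n, m)
  is_min[, 2:(m - 1L)] <- (Rg[, 2:(m - 1L)] < Rg[, 1:(m - 2L)]) &
    (Rg[, 2:(m - 1L)] <= Rg[, 3:m])
  is_min[, 1L] <- Rg[, 1L] < Rg[, 2L]
  is_min[, m] <- Rg[, m] < Rg[, m - 1L]

  degenerate <- abs(rowSums(Mod(S)^2)) < (1e-9 * max(mag))^2 * 3
  pick2 <- function(i) {
    mins <- which(is_min[i, ])
    if (length(mins) == 0L) return(c(NA_integer_, NA_integer_))
    ord <- mins[order(Rg[i, mins])]
    if (length(ord) == 1L) ord <- c(ord, ord)
    ord[1:2]
  }
  picks <- vapply(seq_len(n), pick2, integer(2))
  g1 <- picks[1, ]; g2 <- picks[2, ]
  g1[is.na(g1)] <- 1L; g2[is.na(g2)] <- 1L

  step <- period / n_grid
  clamp <- function(x) pmin(pmax(x, -period / 2), period / 2)
  ref1 <- .golden_refine(S, te, dfz, clamp(grid[g1] - step),
                         clamp(grid[g1] + step))
  ref2 <- .golden_refine(S, te, dfz, clamp(grid[g2] - step),
                         clamp(grid[g2] + step))
  # keep ordering by refined residual
  swap <- ref2$residual < ref1$residual
  for (fld in c("psi", "residual", "W", "F")) {
    tmp <- ref1[[fld]][swap]
    ref1[[fld]][swap] <- ref2[[fld]][swap]
    ref2[[fld]][swap] <- tmp
  }
  # degenerate voxels: coincident zero candidates
  for (ref in c("ref1", "ref2")) {
    r <- get(ref)
    r$psi[degenerate] <- 0; r$residual[degenerate] <- 0
    r$W[degenerate] <- 0; r$F[degenerate] <- 0
    assign(ref, r)
  }
  arr <- function(v) {
    a <- array(NA_real_, dim = d[1:3]); a[idx] <- v; a
  }
  darr <- array(FALSE, dim = d[1:3]); darr[idx] <- degenerate
  structure(
    list(psi1 = arr(ref1$psi),
         psi2 = arr(ref2$psi),
         r1 = arr(ref1$residual), r2 = arr(ref2$residual),
         W1 = arr(ref1$W), F1 = arr(ref1$F),
         W2 = arr(ref2$W), F2 = arr(ref2$F),
         magnitude = mag, degenerate = darr, mask = mask,
         period = period, protocol = series$protocol),
    class = "candidate_field")
}

#' Resolve the off-resonance field from per-voxel candidates
#'
#' Selects one of the two candidate phasors per voxel so that the field is
#' spatially smooth: region growing, per slice, from the highest-magnitude
#' seed voxel (taking its water-dominant candidate as the anchor, falling
#' back to the lower-residual one), with every visited voxel adopting the
#' candidate closest in phasor angle to the mean phasor of its
#' already-resolved neighbors in a 3 x 3 window. Visits proceed in
#' descending magnitude order so high-signal voxels anchor the field.
#'
#' @param cands A `candidate_field`.
#' @param mask Optional logical array further restricting the candidates'
#'   mask.
#' @return List with `psi` (Hz, NA outside the mask) and `selection`
#'   (integer array: 1 first candidate, 2 second, 0 outside).
#' @export
resolve_phasor_field <- function(cands, mask = NULL) {
  stopifnot(inherits(cands, "candidate_field"))
  m <- cands$mask
  if (!is.null(mask)) m <- m & mask
  d <- dim(m)
  psi <- array(NA_real_, dim = d)
  selection <- array(0L, dim = d)
  if (!any(m)) return(list(psi = psi, selection = selection))
  dte_factor <- 2 * pi / cands$period   # angle = 2 pi psi dTE
  for (s in seq_len(d[1])) {
    sl <- function(a) matrix(a[s, , ], d[2], d[3])
    msk <- sl(m) > 0
    if (!any(msk)) next
    a1 <- sl(cands$psi1) * dte_factor
    a2 <- sl(cands$psi2) * dte_factor
    mag <- sl(cands$magnitude)
    seed_idx <- which(msk)[which.max(mag[msk])]
    seed_rc <- arrayInd(seed_idx, dim(msk))
    w1 <- sl(cands$W1)[seed_idx]; f1 <- sl(cands$F1)[seed_idx]
    w2 <- sl(cands$W2)[seed_idx]; f2 <- sl(cands$F2)[seed_idx]
    seed_choice <- if (w1 >= f1) 1L else if (w2 >= f2) 2L else 1L
    a1[is.na(a1)] <- 0; a2[is.na(a2)] <- 0
    sel <- rg_resolve(a1, a2, mag, msk,
                      seed_rc[1] - 1L, seed_rc[2] - 1L, seed_choice)
    chosen <- ifelse(sel == 1L, sl(cands$psi1),
                     ifelse(sel == 2L, sl(cands$psi2), NA_real_))
    # in-mask voxels unreachable from the seed (disconnected specks) fall
    # back to their lower-residual candidate
    orphan <- msk & sel == 0L
    if (any(orphan)) {
      chosen[orphan] <- cands$psi1[s, , ][orphan]
      sel[orphan] <- 1L
    }
    psi[s, , ] <- chosen
    selection[s, , ] <- sel
  }
  list(psi = psi, selection = selection)
}

#' Three-point Dixon water/fat decomposition
#'
#' Full per-volume pipeline: per-voxel candidate extraction
#' ([three_point_candidates()]), smoothness-driven off-resonance resolution
#' ([resolve_phasor_field()]), and a final non-negative amplitude fit at
#' the selected field, yielding water, fat, fat-fraction, field and
#' residual maps.
#'
#' @param series An `echo_series` with exactly 3 complex echoes.
#' @param mask Optional logical array restricting the fit.
#' @param n_grid Coarse grid size passed to [three_point_candidates()].
#' @return An object of class `fat_water_result` with arrays `W`, `F`,
#'   `FF`, `psi`, `residual` (zero/NA outside the mask), the `mask`,
#'   `method = "three_point"` and the protocol.
#' @export
decompose_three_point <- function(series, mask = NULL, n_grid = 96L) {
  cands <- three_point_candidates(series, mask, n_grid = n_grid)
  res <- resolve_phasor_field(cands)
  d <- dim(cands$mask)
  idx <- which(cands$mask)
  te <- series$protocol$echo_times / 1000
  dfz <- fat_water_offset(series$protocol)
  flat <- matrix(series$data, ncol = 3)
  fit <- .fw_fit(flat[idx, , drop = FALSE], te, dfz, res$psi[idx])
  zero <- function(v) { a <- array(0, dim = d); a[idx] <- v; a }
  W <- zero(fit$W); F_ <- zero(fit$F)
  structure(
    list(W = W, F = F_, FF = fat_fraction(W, F_),
         psi = res$psi, residual = zero(fit$residual),
         selection = res$selection,
         mask = cands$mask, method = "three_point",
         magnitude_only = FALSE, protocol = series$protocol),
    class = "fat_water_result")
}

#' Two-point (dual-echo) Dixon decomposition
#'
#' Treats the first echo as nominal opposed-phase and the second as nominal
#' in-phase. With complex data the smooth error-phasor field is estimated
#' from the squared inter-echo phasor `(s2 * Conj(s1))^2` (squaring
#' removes the sign of the opposed-phase magnitude), smoothed per slice
#' with a Gaussian kernel, halved in phase, converted to an off-resonance
#' estimate, and used to demodulate both echoes before
#' `W = (IP + OP)/2`, `F = (IP - OP)/2` with non-negativity clamping.
#' Magnitude-only input falls back to `W = (|s2| + |s1|)/2`,
#' `F = (|s2| - |s1|)/2` clamped at zero, in which case fat-dominant voxels
#' are unresolvable (flagged in the result).
#'
#' @param series An `echo_series` with exactly 2 echoes.
#' @param mask Optional logical array; `NULL` uses all voxels.
#' @param phasor_sigma Gaussian smoothing scale (voxels) for the error
#'   phasor.
#' @return A `fat_water_result` with `method = "two_point"`.
#' @export
decompose_two_point <- function(series, mask = NULL, phasor_sigma = 6) {
  stopifnot(inherits(series, "echo_series"))
  d <- dim(series$data)
  if (d[4] != 2L) stop("two-point decomposition requires exactly 2 echoes")
  te <- series$protocol$echo_times / 1000
  if (is.null(mask)) mask <- array(TRUE, dim = d[1:3])
  if (series$magnitude_only) {
    op <- array(series$data[, , , 1], dim = d[1:3])
    ip <- array(series$data[, , , 2], dim = d[1:3])
    W <- pmax((ip + op) / 2, 0)
    F_ <- pmax((ip - op) / 2, 0)
    psi <- array(0, dim = d[1:3])
    resid <- array(0, dim = d[1:3])
  } else {
    s1 <- array(series$data[, , , 1], dim = d[1:3])
    s2 <- array(series$data[, , , 2], dim = d[1:3])
    # squared inter-echo phasor: squaring removes the sign flip of the
    # opposed-phase magnitude, so arg(q) ~ 2 * 2 pi psi dTE
    q <- (s2 * Conj(s1))^2
    # keep the Gaussian kernel inside the slice for small images
    sig <- min(phasor_sigma, (min(d[2], d[3]) - 1) / 7)
    qs <- array(complex(real = 0), dim = d[1:3])
    for (s in seq_len(d[1])) {
      qsl <- matrix(q[s, , ], d[2], d[3])
      if (sig >= 0.5) {
        qs[s, , ] <- EBImage::gblur(Re(qsl), sigma = sig) +
          1i * EBImage::gblur(Im(qsl), sigma = sig)
      } else {
        qs[s, , ] <- qsl
      }
    }
    phase <- Arg(qs) / 2
    psi <- phase / (2 * pi * (te[2] - te[1]))
    ph1 <- 2 * pi * psi * te[1]
    ph2 <- 2 * pi * psi * te[2]
    op <- Re(s1 * exp(-1i * ph1))
    ip <- Re(s2 * exp(-1i * ph2))
    W <- pmax((ip + op) / 2, 0)
    F_ <- pmax((ip - op) / 2, 0)
    resid <- Mod(s1 * exp(-1i * ph1) - (W - F_))^2 +
      Mod(s2 * exp(-1i * ph2) - (W + F_))^2
  }
  W[!mask] <- 0; F_[!mask] <- 0
  structure(
    list(W = W, F = F_, FF = fat_fraction(W, F_),
         psi = psi, residual = resid, mask = mask,
         method = "two_point", magnitude_only = series$magnitude_only,
         protocol = series$protocol),
    class = "fat_water_result")
}

#' Fat-fraction map
#'
#' `F / (W + F)` wherever the total signal exceeds an epsilon of
#' `1e-6 * max(W + F)`, else 0.
#'
#' @param W,F Non-negative arrays of equal shape.
#' @return Array of fat fractions in `[0, 1]`.
#' @export
fat_fraction <- function(W, F) {
  if (any(W < 0, na.rm = TRUE) || any(F < 0, na.rm = TRUE))
    stop("fat_fraction requires non-negative W and F")
  stopifnot(all(dim(W) == dim(F)))
  tot <- W + F
  eps <- 1e-6 * max(tot, na.rm = TRUE)
  ff <- array(0, dim = dim(W))
  ok <- !is.na(tot) & tot > eps
  ff[ok] <- F[ok] / tot[ok]
  ff
}

#' @export
print.fat_water_result <- function(x, ...) {
  d <- dim(x$W)
  cat(sprintf("<fat_water_result> %s, %d slices x %d x %d%s\n",
              x$method, d[1], d[2], d[3],
              if (x$magnitude_only) " (magnitude-only input)" else ""))
  cat(sprintf("  FF in body-mask: median %.3f\n",
              stats::median(x$FF[x$mask])))
  invisible(x)
}
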