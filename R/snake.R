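#' Active-contour (snake) parameters
#'
#' Controls the per-slice inward-propagating snake that finds the boundary
#' between subcutaneous fat and the muscle/fascia layer on fat images.
#' Defaults were tuned on the digital phantoms; all are exposed.
#'
#' @param n_vertices Number of contour vertices (>= 16). 120 suits
#'   mouse-scale matrices; 200 human-scale.
#' @param alpha Tension (membrane) weight.
#' @param beta Stiffness (curvature) weight.
#' @param kappa Inward balloon pressure (voxels per step in the absence of
#'   image forces).
#' @param gamma Evolution step size.
#' @param sigma Gaussian smoothing scale (voxels) of the edge map.
#' @param edge_weight Gain applied to the edge-attraction force.
#' @param edge_margin Distance (voxels) from the body-mask boundary within
#'   which the edge map is zeroed, so the contour is not trapped on the
#'   skin/outer-SCAT edge it starts on.
#' @param max_iter Iteration cap.
#' @param tol Mean vertex displacement (voxels) below which an iteration
#'   counts as converged.
#' @param patience Consecutive converged iterations required to stop.
#' @param resample_every Re-distribute vertices to equal arclength every
#'   this many iterations.
#' @return An object of class `snake_params`.
#' @export
snake_params <- function(n_vertices = 120L, alpha = 0.1, beta = 0.05,
                         kappa = 0.3, gamma = 1, sigma = 2,
                         edge_weight = 2, edge_margin = 4,
                         max_iter = 500L, tol = 0.05, patience = 5L,
                         resample_every = 10L) {
  stopifnot(n_vertices >= 16L, alpha >= 0, beta >= 0, kappa >= 0,
            gamma > 0, sigma > 0, edge_weight >= 0, edge_margin >= 0,
            max_iter >= 1L, tol > 0, patience >= 1L, resample_every >= 1L)
  structure(list(n_vertices = as.integer(n_vertices), alpha = alpha,
                 beta = beta, kappa = kappa, gamma = gamma, sigma = sigma,
                 edge_weight = edge_weight, edge_margin = edge_margin,
                 max_iter = as.integer(max_iter), tol = tol,
                 patience = as.integer(patience),
                 resample_every = as.integer(resample_every)),
            class = "snake_params")
}

# signed area of a closed polygon in (x = col, y = row) coordinates
.poly_area <- function(xy) {
  y <- xy[, 1]; x <- xy[, 2]
  y2 <- c(y[-1], y[1]); x2 <- c(x[-1], x[1])
  sum(x * y2 - x2 * y) / 2
}

.make_contour <- function(xy, slice = NA_integer_, component = NA_integer_) {
  structure(xy, class = c("snake_contour", "matrix", "array"),
            slice = slice, component = component)
}

#' Resample a closed contour to equidistant vertices
#'
#' Arclength-uniform resampling of a closed polygon; the first vertex is
#' kept as the starting point, so resampling an already-uniform contour is
#' idempotent up to floating-point error.
#'
#' @param xy n x 2 matrix of vertex coordinates (row, col).
#' @param n Number of output vertices.
#' @return n x 2 matrix.
#' @export
resample_contour <- function(xy, n) {
  xy <- unclass(xy)[, 1:2, drop = FALSE]
  once <- function(xy) {
    m <- nrow(xy)
    closed <- rbind(xy, xy[1, , drop = FALSE])
    seg <- sqrt(rowSums(diff(closed)^2))
    cum <- c(0, cumsum(seg))
    total <- cum[m + 1]
    target <- seq(0, total, length.out = n + 1L)[seq_len(n)]
    r <- stats::approx(cum, closed[, 1], xout = target, ties = "ordered")$y
    c_ <- stats::approx(cum, closed[, 2], xout = target, ties = "ordered")$y
    cbind(r, c_, deparse.level = 0)
  }
  # iterate to the fixed point: equal arclength on the *new* polygon, so
  # repeated resampling is idempotent to floating-point precision
  out <- once(xy)
  for (i in 1:50) {
    nxt <- once(out)
    if (nrow(nxt) == nrow(out) && max(abs(nxt - out)) < 1e-12) {
      out <- nxt
      break
    }
    out <- nxt
  }
  out
}

#' Extract the outer skin contour of a body-mask component
#'
#' Boundary polygon of a connected mask component, resampled to
#' `n_vertices` equidistant vertices with a fixed (counter-clockwise in
#' image coordinates) orientation. This is the initial contour for the
#' inward snake propagation.
#'
#' @param mask Logical or 0/1 matrix containing a single connected
#'   component.
#' @param n_vertices Number of contour vertices.
#' @param slice,component Bookkeeping indices stored as attributes.
#' @return A `snake_contour` (n x 2 matrix of 0-based voxel-centre
#'   (row, col) coordinates).
#' @export
outer_contour <- function(mask, n_vertices = 120L, slice = NA_integer_,
                          component = NA_integer_) {
  mask <- (mask > 0) * 1L
  if (!any(mask == 1L)) stop("empty mask component")
  oc <- EBImage::ocontour(mask)
  # largest boundary if several objects slipped through
  lens <- vapply(oc, nrow, integer(1))
  xy <- oc[[which.max(lens)]] * 1.0   # 0-based (row, col)
  if (nrow(xy) < 4L) {
    # pathological small component: build a tiny square around its voxels
    idx <- which(mask == 1L, arr.ind = TRUE) - 1L
    ctr <- colMeans(idx)
    th <- seq(0, 2 * pi, length.out = 17L)[-17L]
    xy <- cbind(ctr[1] + 0.5 * sin(th), ctr[2] + 0.5 * cos(th))
  }
  nv <- n_vertices
  if (nrow(xy) < nv) {
    nv <- max(16L, nrow(xy))
    message("contour has fewer boundary pixels than requested vertices; ",
            "using ", nv)
  }
  if (.poly_area(xy) < 0) xy <- xy[rev(seq_len(nrow(xy))), , drop = FALSE]
  .make_contour(resample_contour(xy, nv), slice, component)
}

# bilinear interpolation of matrix values at 0-based (row, col) positions
.interp2 <- function(M, r, c_) {
  nr <- nrow(M); nc <- ncol(M)
  r <- pmin(pmax(r, 0), nr - 1); c_ <- pmin(pmax(c_, 0), nc - 1)
  r0 <- pmin(floor(r), nr - 2); c0 <- pmin(floor(c_), nc - 2)
  fr <- r - r0; fc <- c_ - c0
  i00 <- cbind(r0 + 1, c0 + 1); i10 <- cbind(r0 + 2, c0 + 1)
  i01 <- cbind(r0 + 1, c0 + 2); i11 <- cbind(r0 + 2, c0 + 2)
  M[i00] * (1 - fr) * (1 - fc) + M[i10] * fr * (1 - fc) +
    M[i01] * (1 - fr) * fc + M[i11] * fr * fc
}

# edge map: gradient magnitude of the Gaussian-smoothed image, normalized,
# with a margin near the body-mask boundary suppressed
.edge_map <- function(img, sigma, body_mask = NULL, edge_margin = 0) {
  img <- img / max(max(img), .Machine$double.eps)
  G <- EBImage::gblur(img, sigma = sigma)
  nr <- nrow(G); nc <- ncol(G)
  gy <- G; gx <- G
  gy[2:(nr - 1), ] <- (G[3:nr, ] - G[1:(nr - 2), ]) / 2
  gy[c(1, nr), ] <- 0
  gx[, 2:(nc - 1)] <- (G[, 3:nc] - G[, 1:(nc - 2)]) / 2
  gx[, c(1, nc)] <- 0
  E <- sqrt(gy^2 + gx^2)
  m <- max(E)
  if (m > 0) E <- E / m
  if (!is.null(body_mask) && edge_margin > 0) {
    dm <- EBImage::distmap((body_mask > 0) * 1)
    E[dm <= edge_margin] <- 0
  }
  E
}

#' Evolve a snake to the deep (SCAT/muscle) boundary
#'
#' Semi-implicit evolution of a closed parametric contour minimizing
#' tension + stiffness internal energy plus an external energy
#' `-|grad(G_sigma * I_fat)|`, with a constant inward balloon pressure.
#' Starting from the outer skin contour, the balloon drives the contour
#' inward through the subcutaneous fat until it locks onto the sharp
#' fat-signal edge at the fascia. Terminates when the mean vertex
#' displacement stays below `tol` for `patience` iterations, at `max_iter`
#' (flagged unconverged), or on area collapse (flagged).
#'
#' @param init A `snake_contour` (e.g. from [outer_contour()]).
#' @param fat_slice 2D fat-signal image.
#' @param params A [snake_params()].
#' @param body_mask Optional logical matrix used to suppress edges within
#'   `edge_margin` of the body boundary.
#' @return A `snake_contour` with attributes `converged`, `collapsed`,
#'   `iterations`, `radius_trace` and `energy_trace`.
#' @export
evolve_snake <- function(init, fat_slice, params = snake_params(),
                         body_mask = NULL) {
  stopifnot(inherits(params, "snake_params"))
  V <- unclass(init)[, 1:2, drop = FALSE]
  n <- nrow(V)
  E <- .edge_map(fat_slice, params$sigma, body_mask, params$edge_margin)
  nr <- nrow(E); nc <- ncol(E)
  Fy <- E; Fx <- E
  Fy[2:(nr - 1), ] <- (E[3:nr, ] - E[1:(nr - 2), ]) / 2
  Fy[c(1, nr), ] <- 0
  Fx[, 2:(nc - 1)] <- (E[, 3:nc] - E[, 1:(nc - 2)]) / 2
  Fx[, c(1, nc)] <- 0

  # pentadiagonal internal-energy operator (circulant)
  ix <- seq_len(n)
  nxt <- c(ix[-1], 1L); prv <- c(n, ix[-n])
  D2 <- matrix(0, n, n)
  D2[cbind(ix, ix)] <- -2; D2[cbind(ix, nxt)] <- 1; D2[cbind(ix, prv)] <- 1
  D4 <- D2 %*% D2
  A <- -params$alpha * D2 + params$beta * D4
  M <- solve(diag(n) + params$gamma * A)

  energy <- function(V) {
    dv <- V[nxt, ] - V
    d2v <- V[nxt, ] - 2 * V + V[prv, ]
    params$alpha * sum(dv^2) + params$beta * sum(d2v^2) -
      params$edge_weight * sum(.interp2(E, V[, 1], V[, 2])) +
      params$kappa * abs(.poly_area(V))
  }

  radius_trace <- numeric(0)
  energy_trace <- numeric(0)
  converged <- FALSE; collapsed <- FALSE
  still <- 0L
  it <- 0L
  while (it < params$max_iter) {
    it <- it + 1L
    # inward normals (orientation enforced positive-area)
    if (.poly_area(V) < 0) V <- V[rev(ix), , drop = FALSE]
    tng <- (V[nxt, , drop = FALSE] - V[prv, , drop = FALSE]) / 2
    len <- sqrt(rowSums(tng^2)); len[len == 0] <- 1
    # outward normal in (x=col, y=row) plane is (t_y, -t_x); see .poly_area
    n_out <- cbind(-tng[, 2], tng[, 1]) / len   # (row, col) components
    f_ext <- params$edge_weight *
      cbind(.interp2(Fy, V[, 1], V[, 2]), .interp2(Fx, V[, 1], V[, 2])) -
      params$kappa * n_out
    Vn <- M %*% (V + params$gamma * f_ext)
    Vn[, 1] <- pmin(pmax(Vn[, 1], 0), nr - 1)
    Vn[, 2] <- pmin(pmax(Vn[, 2], 0), nc - 1)
    disp <- mean(sqrt(rowSums((Vn - V)^2)))
    V <- Vn
    if (it %% params$resample_every == 0L) V <- resample_contour(V, n)
    ctr <- colMeans(V)
    radius_trace <- c(radius_trace,
                      mean(sqrt(rowSums(sweep(V, 2, ctr)^2))))
    energy_trace <- c(energy_trace, energy(V))
    if (abs(.poly_area(V)) < 4) { collapsed <- TRUE; break }
    if (disp < params$tol) {
      still <- still + 1L
      if (still >= params$patience) { converged <- TRUE; break }
    } else still <- 0L
  }
  if (!converged && !collapsed)
    warning("snake did not converge within max_iter = ", params$max_iter)
  out <- .make_contour(V, attr(init, "slice"), attr(init, "component"))
  attr(out, "converged") <- converged
  attr(out, "collapsed") <- collapsed
  attr(out, "iterations") <- it
  attr(out, "radius_trace") <- radius_trace
  attr(out, "energy_trace") <- energy_trace
  out
}
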