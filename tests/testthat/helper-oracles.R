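# Independent least-squares oracle for the chemical-shift signal model.
# Projection-matrix route on the stacked real/imaginary design (distinct
# from the package's scalar normal-equation implementation); non-negativity
# handled by explicit active-set cases.
oracle_fw_fit <- function(S, te_s, dfz, psi) {
  if (is.null(dim(S))) S <- matrix(S, nrow = 1)
  K <- length(te_s)
  ck <- exp(1i * 2 * pi * dfz * te_s)
  X <- rbind(cbind(rep(1, K), Re(ck)), cbind(rep(0, K), Im(ck)))
  P <- solve(crossprod(X)) %*% t(X)
  psi <- rep(psi, length.out = nrow(S))
  D <- S * exp(-1i * 2 * pi * outer(psi, te_s))
  Y <- cbind(Re(D), Im(D))
  B <- Y %*% t(P)
  W <- B[, 1]; F <- B[, 2]
  fixF <- F < 0
  if (any(fixF)) {
    W[fixF] <- pmax(rowMeans(Re(D))[fixF], 0)
    F[fixF] <- 0
  }
  fixW <- !fixF & W < 0
  if (any(fixW)) {
    F[fixW] <- pmax(Re(D[fixW, , drop = FALSE] %*% Conj(ck))[, 1] / K, 0)
    W[fixW] <- 0
  }
  R <- rowSums((Y - cbind(W, F) %*% t(X))^2)
  list(W = W, F = F, residual = R)
}

# Brute-force grid search of the residual profile R(psi) over one aliasing
# period; returns the grid and the n x G residual matrix.
oracle_grid <- function(S, protocol, step = 1) {
  if (is.null(dim(S))) S <- matrix(S, nrow = 1)
  te_s <- protocol$echo_times / 1000
  dfz <- fat_water_offset(protocol)
  period <- 1 / (te_s[2] - te_s[1])
  grid <- seq(-period / 2, period / 2, by = step)
  R <- matrix(0, nrow(S), length(grid))
  for (g in seq_along(grid))
    R[, g] <- oracle_fw_fit(S, te_s, dfz, grid[g])$residual
  list(grid = grid, R = R, period = period)
}

# indices of local minima of a residual vector over an (interval) grid;
# endpoints count when they are lower than their single neighbor
grid_minima <- function(r) {
  m <- length(r)
  c(if (r[1] < r[2]) 1L,
    1L + which(r[2:(m - 1)] < r[1:(m - 2)] & r[2:(m - 1)] <= r[3:m]),
    if (r[m] < r[m - 1]) m)
}

# analytic model signals for one voxel
model_signal <- function(W, F, psi, protocol, phi0 = 0) {
  te_s <- protocol$echo_times / 1000
  dfz <- fat_water_offset(protocol)
  (W + F * exp(1i * 2 * pi * dfz * te_s)) *
    exp(1i * (phi0 + 2 * pi * psi * te_s))
}

# minimal in-memory echo series around a plain signal matrix (n voxels x K)
synthetic_series <- function(S, protocol, magnitude_only = FALSE) {
  n <- nrow(S)
  structure(
    list(data = array(if (magnitude_only) abs(S) else S,
                      dim = c(1, n, 1, ncol(S))),
         protocol = protocol, magnitude_only = magnitude_only,
         truth = NULL, seed = NA_integer_),
    class = "echo_series")
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
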