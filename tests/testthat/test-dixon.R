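mouse_pr <- protocol_preset("mouse7t")

test_that("residual_profile inverts the model at the true off-resonance", {
  s <- model_signal(1, 0, 0, mouse_pr)
  at0 <- residual_profile(s, mouse_pr, 0)
  expect_lt(at0$residual, 1e-20)
  expect_equal(at0$W, 1, tolerance = 1e-10)
  expect_equal(at0$F, 0, tolerance = 1e-10)
  # a wrong psi must misfit
  off <- residual_profile(s, mouse_pr, 120)
  expect_gt(off$residual, 1e-4)
  # all-zero signal fits trivially
  z <- residual_profile(c(0 + 0i, 0, 0), mouse_pr, 37)
  expect_equal(z$residual, 0)
  expect_equal(z$W, 0)
  expect_equal(z$F, 0)
})

test_that("residual_profile agrees with the independent projection oracle", {
  set.seed(21)
  n <- 200
  W <- runif(n, 0, 2); F_ <- runif(n, 0, 2)
  psi0 <- runif(n, -400, 400)
  S <- t(vapply(seq_len(n),
                function(i) model_signal(W[i], F_[i], psi0[i], mouse_pr),
                complex(3)))
  S <- S + matrix(complex(real = rnorm(3 * n, 0, 0.02),
                          imaginary = rnorm(3 * n, 0, 0.02)), n, 3)
  for (psi_eval in c(-500, 0, 123.4)) {
    mine <- residual_profile(S, mouse_pr, psi_eval)
    orac <- oracle_fw_fit(S, mouse_pr$echo_times / 1000,
                          fat_water_offset(mouse_pr), psi_eval)
    expect_equal(mine$W, orac$W, tolerance = 1e-8)
    expect_equal(mine$F, orac$F, tolerance = 1e-8)
    expect_equal(mine$residual, orac$residual, tolerance = 1e-8)
  }
})

test_that("the residual profile's global minimum sits at the true field", {
  # mixed voxel W=2, F=1 at psi = 50 Hz: 1 Hz brute-force grid
  s <- model_signal(2, 1, 50, mouse_pr)
  og <- oracle_grid(s, mouse_pr, step = 1)
  at_min <- og$grid[which.min(og$R[1, ])]
  expect_lt(abs(at_min - 50), 1)
  fit <- residual_profile(s, mouse_pr, at_min)
  expect_equal(fit$W, 2, tolerance = 0.02)
  expect_equal(fit$F, 1, tolerance = 0.02)
})

test_that("candidates match the 1 Hz grid-search oracle on random voxels", {
  set.seed(13)
  n <- 1000
  W <- runif(n, 0.1, 2); F_ <- runif(n, 0.1, 2)
  period <- 1 / ((mouse_pr$echo_times[2] - mouse_pr$echo_times[1]) / 1000)
  psi0 <- runif(n, -period / 2, period / 2)
  S <- t(vapply(seq_len(n),
                function(i) model_signal(W[i], F_[i], psi0[i], mouse_pr),
                complex(3)))
  cands <- three_point_candidates(synthetic_series(S, mouse_pr),
                                  mask = array(TRUE, c(1, n, 1)))
  og <- oracle_grid(S, mouse_pr, step = 1)
  p1 <- as.vector(cands$psi1)[seq_len(n)]
  p2 <- as.vector(cands$psi2)[seq_len(n)]
  # the lower-residual candidate agrees with the oracle global minimum
  gmin <- og$grid[apply(og$R, 1, which.min)]
  expect_lt(max(abs(p1 - gmin)), 1)
  # each refined candidate lies within 1 Hz of an oracle local minimum
  err1 <- err2 <- numeric(n)
  for (i in seq_len(n)) {
    opsi <- og$grid[grid_minima(og$R[i, ])]
    err1[i] <- min(abs(p1[i] - opsi))
    err2[i] <- min(abs(p2[i] - opsi))
  }
  expect_lt(max(err1), 1)
  expect_lt(max(err2), 1)
})

test_that("pure voxels produce the expected candidate pair", {
  dfz <- fat_water_offset(mouse_pr)
  # pure water at psi = 0: one candidate at 0 fitting W, the alias fits F
  s_w <- model_signal(1, 0, 0, mouse_pr)
  cw <- three_point_candidates(synthetic_series(matrix(s_w, 1), mouse_pr),
                               mask = array(TRUE, c(1, 1, 1)))
  psis <- c(cw$psi1[1, 1, 1], cw$psi2[1, 1, 1])
  ws <- c(cw$W1[1, 1, 1], cw$W2[1, 1, 1])
  fs <- c(cw$F1[1, 1, 1], cw$F2[1, 1, 1])
  i0 <- which.min(abs(psis))
  expect_lt(abs(psis[i0]), 0.5)
  expect_equal(ws[i0], 1, tolerance = 1e-6)
  expect_equal(fs[i0], 0, tolerance = 1e-6)
  ia <- 3 - i0
  expect_gt(fs[ia], ws[ia])  # swapped alias assigns the amplitude to fat
  expect_lt(min(cw$r1[1, 1, 1], cw$r2[1, 1, 1]), 1e-12)

  # pure fat at psi = 0: the swapped candidate at 0 assigns amplitude to F
  s_f <- model_signal(0, 1, 0, mouse_pr)
  cf <- three_point_candidates(synthetic_series(matrix(s_f, 1), mouse_pr),
                               mask = array(TRUE, c(1, 1, 1)))
  psis_f <- c(cf$psi1[1, 1, 1], cf$psi2[1, 1, 1])
  fs_f <- c(cf$F1[1, 1, 1], cf$F2[1, 1, 1])
  j0 <- which.min(abs(psis_f))
  expect_lt(abs(psis_f[j0]), 0.5)
  expect_equal(fs_f[j0], 1, tolerance = 1e-6)
})

test_that("zero-signal voxels give coincident zero candidates, flagged", {
  S <- rbind(model_signal(1, 0, 0, mouse_pr),
             c(0 + 0i, 0, 0),
             model_signal(0, 1, 0, mouse_pr))
  cz <- three_point_candidates(synthetic_series(S, mouse_pr),
                               mask = array(TRUE, c(1, 3, 1)))
  expect_true(cz$degenerate[1, 2, 1])
  expect_false(cz$degenerate[1, 1, 1])
  expect_equal(cz$psi1[1, 2, 1], 0)
  expect_equal(cz$psi2[1, 2, 1], 0)
  expect_equal(cz$r1[1, 2, 1], 0)
  expect_equal(cz$W1[1, 2, 1], 0)
  expect_equal(cz$F1[1, 2, 1], 0)
})

test_that("swap symmetry: aliased solutions exchange water and fat", {
  # For pure voxels the fat/water swap is exact: a water-only voxel at
  # psi0 is perfectly explained as fat-only at psi0 - dfz, and a fat-only
  # voxel as water-only at psi0 + dfz (single-peak model, numerically).
  dfz <- fat_water_offset(mouse_pr)
  set.seed(5)
  for (i in 1:10) {
    A <- runif(1, 0.2, 2); psi0 <- runif(1, -300, 300)
    sw <- model_signal(A, 0, psi0, mouse_pr)
    alias_w <- residual_profile(sw, mouse_pr, psi0 - dfz)
    expect_lt(alias_w$residual, 1e-12 * A^2)
    expect_equal(alias_w$F, A, tolerance = 1e-8)
    expect_equal(alias_w$W, 0, tolerance = 1e-8)
    sf <- model_signal(0, A, psi0, mouse_pr)
    alias_f <- residual_profile(sf, mouse_pr, psi0 + dfz)
    expect_lt(alias_f$residual, 1e-12 * A^2)
    expect_equal(alias_f$W, A, tolerance = 1e-8)
    expect_equal(alias_f$F, 0, tolerance = 1e-8)
  }
  # For mixed voxels the swap is approximate: at the second-best local
  # minimum the dominant amplitude moves to the other species.
  set.seed(6)
  for (i in 1:10) {
    W <- runif(1, 1.2, 2); F_ <- runif(1, 0.1, 0.6)
    psi0 <- runif(1, -300, 300)
    s <- model_signal(W, F_, psi0, mouse_pr)
    og <- oracle_grid(s, mouse_pr, step = 2)
    mins <- grid_minima(og$R[1, ])
    second <- mins[order(og$R[1, mins])][2]
    fit2 <- residual_profile(s, mouse_pr, og$grid[second])
    expect_gt(fit2$F, fit2$W)   # water-dominant voxel looks fat-dominant
    s_fdom <- model_signal(F_, W, psi0, mouse_pr)
    og2 <- oracle_grid(s_fdom, mouse_pr, step = 2)
    mins2 <- grid_minima(og2$R[1, ])
    second2 <- mins2[order(og2$R[1, mins2])][2]
    fit2b <- residual_profile(s_fdom, mouse_pr, og2$grid[second2])
    expect_gt(fit2b$W, fit2b$F)
  }
})

test_that("phasor resolution recovers a constant field without swaps", {
  fx <- mouse_noisefree()
  pr <- fx$spec$protocol
  te <- pr$echo_times / 1000
  psi0 <- 65
  se <- fx$series
  data <- simulate_echoes(fx$anatomy, pr)$data
  for (k in 1:3) data[, , , k] <- data[, , , k] * exp(1i * 2 * pi * psi0 * te[k])
  sec <- structure(list(data = data, protocol = pr, magnitude_only = FALSE,
                        truth = NULL, seed = 1L), class = "echo_series")
  body <- fx$anatomy$tissue > 0
  cands <- three_point_candidates(sec, mask = body)
  res <- resolve_phasor_field(cands)
  expect_lt(max(abs(res$psi[body] - psi0)), 0.5)
})

test_that("a single-voxel mask returns its lower-residual candidate", {
  set.seed(3)
  s <- model_signal(1.2, 0.2, 30, mouse_pr) +
    complex(real = rnorm(3, 0, 0.01), imaginary = rnorm(3, 0, 0.01))
  se <- synthetic_series(matrix(s, 1), mouse_pr)
  cands <- three_point_candidates(se, mask = array(TRUE, c(1, 1, 1)))
  res <- resolve_phasor_field(cands)
  expect_equal(res$selection[1, 1, 1], 1L)
  expect_equal(res$psi[1, 1, 1], cands$psi1[1, 1, 1])
  # empty mask yields an empty map
  res0 <- resolve_phasor_field(cands, mask = array(FALSE, c(1, 1, 1)))
  expect_true(all(is.na(res0$psi)))
})

test_that("noise-free three-point decomposition recovers FF exactly", {
  fx <- mouse_noisefree()
  fw <- decompose_three_point(fx$series)
  body <- fx$anatomy$tissue > 0
  err <- abs(fw$FF - true_ff(fx$anatomy))[body & fw$mask]
  expect_lt(max(err), 0.01)
  # all-water phantom: FF ~ 0 in the whole body
  spec0 <- phantom_spec("mouse", n_slices = 1, vat_n = 0,
                        scat_thickness = 0.5, lean_ff = 0, seed = 2)
  an0 <- build_phantom(spec0)
  an0$fat[] <- 0; an0$water[an0$tissue > 0] <- 1
  fw0 <- decompose_three_point(simulate_echoes(an0, b0_amplitude = 20))
  expect_lt(max(fw0$FF[an0$tissue > 0 & fw0$mask]), 0.01)
})

test_that("noisy three-point decomposition stays accurate at SNR 30", {
  fx <- mouse_snr30()
  fw <- mouse_fw_snr30()
  body <- fx$anatomy$tissue > 0
  sel <- body & fw$mask
  rmse <- sqrt(mean((fw$FF - true_ff(fx$anatomy))[sel]^2))
  expect_lt(rmse, 0.05)
  # swapped voxels: selected field further than half the aliasing offset
  dfz <- abs(fat_water_offset(fx$spec$protocol))
  swap_frac <- mean(abs(fw$psi - fx$series$truth$psi)[sel] > dfz / 2)
  expect_lt(swap_frac, 0.01)
  # non-negativity and FF range invariants
  expect_true(all(fw$W >= 0) && all(fw$F >= 0))
  expect_true(all(fw$FF >= 0 & fw$FF <= 1))
  expect_true(all(fw$residual >= 0))
  expect_error(decompose_three_point(
    structure(list(data = fx$series$data[, , , 1:2, drop = FALSE],
                   protocol = fx$spec$protocol, magnitude_only = FALSE),
              class = "echo_series")), "3 echoes")
})

test_that("two-point decomposition handles the nominal IP/OP arithmetic", {
  hp <- protocol_preset("human3t")
  # noise-free voxel with zero phase error, nominal OP/IP signals
  S <- matrix(complex(real = c(0.6, 1.0)), 1, 2)  # OP = 0.6, IP = 1.0
  d <- array(0 + 0i, c(1, 8, 8, 2))
  d[, , , 1] <- 0.6; d[, , , 2] <- 1.0
  se <- structure(list(data = d, protocol = hp, magnitude_only = FALSE,
                       truth = NULL, seed = 1L), class = "echo_series")
  fw <- decompose_two_point(se)
  expect_equal(unique(as.vector(fw$W)), 0.8, tolerance = 1e-10)
  expect_equal(unique(as.vector(fw$F)), 0.2, tolerance = 1e-10)
  expect_error(decompose_two_point(mouse_noisefree()$series), "2 echoes")
})

test_that("magnitude-only two-point swaps pure fat (documented limitation)", {
  hp <- protocol_preset("human3t")
  d <- array(0, c(1, 4, 4, 2))
  d[, , , 1] <- 1   # |W - F| with W=0, F=1
  d[, , , 2] <- 1   # |W + F|
  se <- structure(list(data = d, protocol = hp, magnitude_only = TRUE,
                       truth = NULL, seed = 1L), class = "echo_series")
  fw <- decompose_two_point(se)
  expect_true(fw$magnitude_only)
  expect_equal(unique(as.vector(fw$W)), 1)
  expect_equal(unique(as.vector(fw$F)), 0)
})

test_that("two-point decomposition is accurate on a human-scale phantom", {
  fx <- human_small()
  fw <- decompose_two_point(fx$series)
  body <- fx$anatomy$tissue > 0
  water_dom <- body & true_ff(fx$anatomy) < 0.5
  rmse <- sqrt(mean((fw$FF - true_ff(fx$anatomy))[water_dom]^2))
  expect_lt(rmse, 0.05)
})

test_that("fat_fraction follows the epsilon rule and rejects negatives", {
  expect_equal(fat_fraction(array(1, 1), array(1, 1))[1], 0.5)
  expect_equal(fat_fraction(array(2, 1), array(1, 1))[1], 1 / 3)
  expect_equal(fat_fraction(array(0, 1), array(0, 1))[1], 0)
  W <- array(c(1, 0), 2); F_ <- array(c(1, 0), 2)
  expect_equal(fat_fraction(W, F_), array(c(0.5, 0), 2))
  expect_error(fat_fraction(array(-1, 1), array(1, 1)), "non-negative")
})
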