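test_that("body masking thresholds, fills and filters components", {
  expect_equal(sum(body_mask(matrix(0, 32, 32))), 0)
  # phantom slice: mask area within 2% of ground-truth body area
  fx <- mouse_noisefree()
  total <- abs(fx$series$data[1, , , 1])
  bm <- body_mask(total)
  truth_area <- sum(fx$anatomy$tissue[1, , ] > 0)
  expect_lt(abs(sum(bm > 0) - truth_area) / truth_area, 0.02)
  expect_equal(attr(bm, "n_components"), 1L)
  # two-component slice (e.g. legs) keeps both components
  two <- matrix(0, 60, 60)
  two[10:25, 10:25] <- 1
  two[35:55, 30:50] <- 1
  bm2 <- body_mask(two, min_area = 20)
  expect_equal(attr(bm2, "n_components"), 2L)
  expect_equal(bm2[40, 40], 1L)  # larger component labeled first
  expect_equal(bm2[15, 15], 2L)
  # tiny specks fall below min_area
  speck <- matrix(0, 40, 40); speck[20, 20] <- 1
  expect_equal(attr(body_mask(speck, min_area = 10), "n_components"), 0L)
})

test_that("outer contours recover analytic geometry", {
  n <- 100; ctr <- (n + 1) / 2
  d <- sqrt(outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, "+"))
  circle <- d <= 30
  oc <- outer_contour(circle, 120)
  rad <- sqrt(rowSums(sweep(unclass(oc), 2, c(ctr, ctr) - 1)^2))
  expect_lt(abs(mean(rad) - 30), 0.5)
  # square: perimeter ~ 4 x side within discretization tolerance
  sq <- matrix(0, n, n); sq[31:70, 31:70] <- 1
  ocs <- unclass(outer_contour(sq, 160))
  per <- sum(sqrt(rowSums((rbind(ocs[-1, ], ocs[1, ]) - ocs)^2)))
  expect_lt(abs(per - 160) / 160, 0.05)
  expect_error(outer_contour(matrix(0, 10, 10)), "empty")
})

test_that("contour resampling is idempotent", {
  n <- 80; ctr <- (n + 1) / 2
  d <- sqrt(outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, "+"))
  oc <- unclass(outer_contour(d <= 25, 100))
  again <- resample_contour(oc, 100)
  expect_lt(max(abs(again - resample_contour(again, 100))), 1e-9)
  expect_lt(max(abs(oc - again)), 1e-9)
})

test_that("the snake converges onto the inner edge of a fat annulus", {
  ann <- annulus_slice()
  init <- outer_contour(ann$body, 120)
  snk <- evolve_snake(init, ann$fat, snake_params(), body_mask = ann$body)
  expect_true(attr(snk, "converged"))
  rad <- sqrt(rowSums(sweep(unclass(snk), 2, rep(ann$center0, 2))^2))
  expect_lt(abs(mean(rad) - 20), 1)
  # energy is non-increasing up to a small step-size tolerance
  et <- attr(snk, "energy_trace")
  drop_total <- et[1] - min(et)
  increases <- diff(et)[diff(et) > 0]
  expect_lt(sum(increases), 0.01 * drop_total)
})

test_that("pressure-only dynamics shrink the contour monotonically", {
  ann <- annulus_slice()
  init <- outer_contour(ann$body, 120)
  snk <- evolve_snake(init, matrix(0, 100, 100),
                      snake_params(max_iter = 200))
  rt <- attr(snk, "radius_trace")
  expect_true(all(diff(rt) < 0))
  expect_true(attr(snk, "collapsed"))
})

test_that("a contour at equilibrium stops immediately", {
  ann <- annulus_slice()
  p <- snake_params()
  init <- outer_contour(ann$body, 120)
  snk <- evolve_snake(init, ann$fat, p, body_mask = ann$body)
  again <- evolve_snake(snk, ann$fat, p, body_mask = ann$body)
  expect_true(attr(again, "converged"))
  expect_lte(attr(again, "iterations"), p$patience + 1L)
  expect_lt(mean(sqrt(rowSums((unclass(again) - unclass(snk))^2))), p$tol * 5)
})

test_that("compartment labelling separates SCAT, VAT and LTW", {
  # annulus phantom (no VAT blobs): SCAT Dice >= 0.95, VAT = 0
  spec0 <- phantom_spec("mouse", n_slices = 1, vat_n = 0, seed = 3)
  an0 <- build_phantom(spec0)
  fw0 <- decompose_three_point(simulate_echoes(an0, b0_amplitude = 20))
  seg0 <- segment_volume(fw0)
  expect_gte(dice(seg0$labels == 1, an0$compartments == 1), 0.95)
  expect_equal(sum(seg0$labels == 2), 0)

  # phantom with VAT blobs at SNR 30: VAT Dice >= 0.90
  fx <- mouse_snr30()
  seg <- mouse_seg_snr30()
  expect_gte(dice(seg$labels == 2, fx$anatomy$compartments == 2), 0.90)
  expect_gte(dice(seg$labels == 1, fx$anatomy$compartments == 1), 0.90)
})

test_that("compartment labels partition the body mask exactly", {
  fw <- mouse_fw_snr30()
  seg <- mouse_seg_snr30()
  for (s in seg$slice_range) {
    bm <- body_mask(fw$W[s, , ] + fw$F[s, , ])
    expect_identical(seg$labels[s, , ] > 0, bm > 0)
  }
})

test_that("an exclusion mask removes a VAT blob from the VAT volume", {
  fx <- mouse_snr30()
  fw <- mouse_fw_snr30()
  blob <- fx$anatomy$geometry$blobs[1, ]
  pr <- fx$spec$protocol
  nr <- pr$matrix_size[1]; nc <- pr$matrix_size[2]
  y <- (seq_len(nr) - (nr + 1) / 2) * pr$in_plane_spacing[1]
  x <- (seq_len(nc) - (nc + 1) / 2) * pr$in_plane_spacing[2]
  disk <- outer((y - blob$cy)^2, (x - blob$cx)^2, "+") <= (blob$r * 1.2)^2
  excl <- array(FALSE, dim = dim(fw$W))
  for (s in seq_len(dim(fw$W)[1])) excl[s, , ] <- disk
  seg_x <- segment_volume(fw, exclusions = excl)
  seg <- mouse_seg_snr30()
  blob_vox <- sum(fx$anatomy$compartments == 2 &
                    aperm(array(disk, c(nr, nc, dim(fw$W)[1])), c(3, 1, 2)))
  expect_gt(sum(seg_x$labels == 4), 0)
  removed <- sum(seg$labels == 2) - sum(seg_x$labels == 2)
  expect_equal(removed, blob_vox, tolerance = 0.1)
})

test_that("slice_range restricts analysis and volumes sum over it", {
  fw <- mouse_fw_snr30()
  seg_all <- mouse_seg_snr30()
  seg_1 <- segment_volume(fw, slice_range = 1L)
  expect_equal(sum(seg_1$labels[2, , ]), 0)
  v1 <- compartment_volumes(seg_1)
  prof <- axial_profile(seg_all)
  for (comp in c("SCAT", "VAT", "LTW")) {
    expect_equal(v1$volume_mm3[v1$compartment == comp],
                 prof$volume_mm3[prof$slice == 1 & prof$compartment == comp])
  }
})

test_that("segmentation is deterministic and scales with voxel size", {
  fw <- mouse_fw_snr30()
  a <- segment_volume(fw)
  expect_identical(a$labels, mouse_seg_snr30()$labels)
  # halving the resolution roughly quarters in-plane voxel counts
  proto_lo <- acquisition_protocol(7, c(1.26, 1.6, 1.94),
                                   protocol_preset("mouse7t")$in_plane_spacing * 2,
                                   2, c(81, 96))
  spec_lo <- phantom_spec("mouse", protocol = proto_lo, n_slices = 1, seed = 7)
  spec_hi <- phantom_spec("mouse", n_slices = 1, seed = 7)
  n_hi <- true_volumes(build_phantom(spec_hi))
  n_lo <- true_volumes(build_phantom(spec_lo))
  ratio <- unname(n_hi$voxels[n_hi$compartment == "SCAT"] /
                    n_lo$voxels[n_lo$compartment == "SCAT"])
  expect_equal(ratio, 4, tolerance = 0.05)
})

test_that("manual overrides reassign labels with an audit trail", {
  seg <- mouse_seg_snr30()
  empty <- array(FALSE, dim = dim(seg$labels))
  same <- apply_manual_override(seg, empty, 2)
  expect_identical(same$labels, seg$labels)
  # reassign k SCAT voxels to VAT: counts conserve
  scat_idx <- which(seg$labels == 1)[1:50]
  corr <- empty; corr[scat_idx] <- TRUE
  over <- apply_manual_override(seg, corr, 2)
  expect_equal(sum(over$labels == 1), sum(seg$labels == 1) - 50)
  expect_equal(sum(over$labels == 2), sum(seg$labels == 2) + 50)
  expect_equal(over$audit[[length(over$audit)]]$voxels_changed, 50)
  expect_error(apply_manual_override(seg, corr, 9), "invalid label")
})
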