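# Shared fixtures, built once per test run and cached.
.fx <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fx)) assign(name, force(expr), envir = .fx)
  get(name, envir = .fx)
}

# small mouse-scale phantom (full in-plane matrix, few slices)
mouse_spec_small <- function(...) {
  phantom_spec("mouse", n_slices = 2L, seed = 7L, ...)
}

mouse_noisefree <- function() fixture("mouse_noisefree", {
  spec <- mouse_spec_small()
  an <- build_phantom(spec)
  se <- simulate_echoes(an, b0_amplitude = 30, noise_sd = 0, seed = 7)
  list(spec = spec, anatomy = an, series = se)
})

mouse_snr30 <- function() fixture("mouse_snr30", {
  spec <- mouse_spec_small(b0_amplitude = 40, noise_sd = 1 / 30)
  an <- build_phantom(spec)
  se <- simulate_echoes(an, b0_amplitude = 40, noise_sd = 1 / 30, seed = 7)
  list(spec = spec, anatomy = an, series = se)
})

mouse_fw_snr30 <- function() fixture("mouse_fw_snr30", {
  decompose_three_point(mouse_snr30()$series)
})

mouse_seg_snr30 <- function() fixture("mouse_seg_snr30", {
  segment_volume(mouse_fw_snr30())
})

true_ff <- function(anatomy) {
  tot <- anatomy$water + anatomy$fat
  ff <- array(0, dim = dim(tot))
  inb <- tot > 0
  ff[inb] <- anatomy$fat[inb] / tot[inb]
  ff
}

# small human-scale dual-echo phantom
human_small <- function() fixture("human_small", {
  proto <- acquisition_protocol(3, c(1.32, 2.46), c(2.6, 2.6), 3.1,
                                c(128, 128))
  spec <- phantom_spec("human", n_slices = 2L, protocol = proto,
                       semi_axes = c(110, 140),
                       b0_amplitude = 30, noise_sd = 1 / 30, seed = 11L)
  an <- build_phantom(spec)
  se <- simulate_echoes(an, b0_amplitude = 30, noise_sd = 1 / 30, seed = 11)
  list(spec = spec, anatomy = an, series = se)
})

# analytic annulus: fat ring between radii 20 and 30 voxels in 100x100
annulus_slice <- function(r_in = 20, r_out = 30, n = 100) {
  ctr <- (n + 1) / 2
  d <- sqrt(outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, "+"))
  list(fat = (d <= r_out & d > r_in) * 1,
       body = d <= r_out,
       dist = d, center0 = ctr - 1)  # 0-based center
}
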