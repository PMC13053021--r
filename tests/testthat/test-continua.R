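test_that("CIELAB interpolation is affine with exact endpoints", {
  A <- lab_colour(73.03, -19.98, 37.84)
  B <- lab_colour(87.24, -62.94, 41.00)
  cc <- interpolate_lab(A, B, 50, "blue", "green")
  expect_equal(nrow(cc), 50)
  expect_identical(unlist(cc[1, c("L", "a", "b")], use.names = FALSE),
                   unname(unclass(A)))
  expect_identical(unlist(cc[50, c("L", "a", "b")], use.names = FALSE),
                   unname(unclass(B)))
  # elementwise affine arithmetic oracle at an interior step
  expect_equal(cc$L[26], 73.03 + (87.24 - 73.03) * 25 / 49, tolerance = 1e-12)
  expect_equal(cc$a[26], -19.98 + (-62.94 + 19.98) * 25 / 49, tolerance = 1e-12)
  # equal spacing: second differences vanish for every coordinate
  for (col in c("L", "a", "b")) {
    expect_lt(max(abs(diff(diff(cc[[col]])))), 1e-10)
  }
  # degenerate endpoints: all steps identical
  same <- interpolate_lab(A, A, 7)
  expect_true(all(same$L == A[["L"]] & same$a == A[["a"]] & same$b == A[["b"]]))
  expect_error(interpolate_lab(A, B, 1), "at least 2")
})

test_that("CIELAB to sRGB conversion matches a reference converter", {
  expect_equal(lab_to_srgb(lab_colour(100, 0, 0))$rgb, c(255L, 255L, 255L))
  expect_equal(lab_to_srgb(lab_colour(0, 0, 0))$rgb, c(0L, 0L, 0L))
  labs <- rbind(
    c(73.03, -19.98, 37.84), c(87.24, -62.94, 41.00),
    c(88.29, -0.98, 69.51), c(68.55, 40.91, 49.37), c(50, 10, -30)
  )
  ref <- grDevices::convertColor(labs, from = "Lab", to = "sRGB",
                                 from.ref.white = "D65", to.ref.white = "D65")
  for (i in seq_len(nrow(labs))) {
    ours <- suppressWarnings(lab_to_srgb(labs[i, ]))$rgb
    expect_true(all(abs(ours - round(ref[i, ] * 255)) <= 5),
                info = paste("row", i))
  }
  expect_match(lab_to_srgb(lab_colour(100, 0, 0))$hex, "^#[0-9a-f]{6}$")
})

test_that("modal interpolation is affine over frequency-paired modes", {
  A <- material_spec("wood", mode_params(1.0, 200, 5))
  B <- material_spec("metal", mode_params(0.5, 400, 15))
  sc <- interpolate_modal(A, B, 10)
  expect_equal(sc$n_steps, 10)
  expect_equal(sc$steps[[1]]$modes, A$modes)   # endpoint identity
  expect_equal(sc$steps[[10]]$modes, B$modes)
  # affine arithmetic oracle at step 5 of 10: fraction 4/9
  m5 <- sc$steps[[5]]$modes
  expect_equal(m5$amplitude, 1 - 0.5 * 4 / 9, tolerance = 1e-12)
  expect_equal(m5$frequency, 200 + 200 * 4 / 9, tolerance = 1e-12)
  expect_equal(m5$decay, 5 + 10 * 4 / 9, tolerance = 1e-12)
  # second differences vanish across steps for every parameter
  amps <- vapply(sc$steps, function(s) s$modes$amplitude[1], numeric(1))
  expect_lt(max(abs(diff(diff(amps)))), 1e-10)
  # modes are paired in ascending-frequency order regardless of input order
  A2 <- material_spec("wood", rbind(mode_params(0.2, 900, 3), mode_params(1, 100, 3)))
  B2 <- material_spec("metal", rbind(mode_params(1, 150, 3), mode_params(0.1, 1000, 3)))
  mid <- interpolate_modal(A2, B2, 3)$steps[[2]]$modes
  expect_equal(mid$frequency, c((100 + 150) / 2, (900 + 1000) / 2))
  expect_error(
    interpolate_modal(A, material_spec("x", rbind(B$modes, B$modes)), 10),
    "equal mode counts"
  )
})

test_that("impact synthesis matches the damped-sinusoid formula", {
  sr <- 8000
  silent <- material_spec("x", mode_params(0, 100, 5))
  expect_true(all(synthesize_impact(silent, sr)$samples == 0))
  # single undamped mode: phase multiple of pi at t = 0.25 s
  pure <- material_spec("x", mode_params(1, 100, 0))
  w <- synthesize_impact(pure, sr)
  expect_equal(length(w$samples), sr)
  expect_equal(w$samples[0.25 * sr + 1], sin(2 * pi * 100 * 0.25), tolerance = 1e-9)
  # two arbitrary modes vs an independently coded oracle
  m <- material_spec("x", rbind(mode_params(0.7, 313, 2.3), mode_params(0.25, 741, 9.1)))
  w2 <- synthesize_impact(m, sr)
  t <- (seq_len(sr) - 1) / sr
  oracle <- 0.7 * exp(-2.3 * t) * sin(2 * pi * 313 * t) +
    0.25 * exp(-9.1 * t) * sin(2 * pi * 741 * t)
  expect_equal(w2$samples, oracle, tolerance = 1e-12)
  # energy decays over time for positive decay rates
  damped <- synthesize_impact(material_spec("x", mode_params(1, 200, 6)), sr)
  h <- length(damped$samples) / 2
  expect_lt(sqrt(mean(damped$samples[(h + 1):(2 * h)]^2)),
            sqrt(mean(damped$samples[1:h]^2)))
  expect_error(synthesize_impact(material_spec("x", mode_params(1, 5000, 1)), 8000),
               "Nyquist|twice")
})

test_that("volume normalisation hits the target RMS and is idempotent", {
  sr <- 8000
  w <- synthesize_impact(material_spec("x", mode_params(0.8, 200, 4)), sr)
  n1 <- normalise_volume(w, 0.1)
  expect_equal(sqrt(mean(n1$samples^2)), 0.1, tolerance = 1e-9)
  n2 <- normalise_volume(n1, 0.1)
  expect_equal(n1$samples, n2$samples, tolerance = 1e-12)
  # shape preserved up to a positive scalar
  expect_equal(n1$samples / max(abs(n1$samples)), w$samples / max(abs(w$samples)),
               tolerance = 1e-12)
  # a whole continuum normalises to a common level
  mats <- default_materials()
  sc <- interpolate_modal(mats$wood, mats$glass, 10)
  rms <- vapply(sc$steps, function(s) {
    sqrt(mean(normalise_volume(synthesize_impact(s, 22050), 0.1)$samples^2))
  }, numeric(1))
  expect_equal(rms, rep(0.1, 10), tolerance = 1e-9)
  zero <- structure(list(samples = rep(0, 10), sample_rate = sr), class = "waveform")
  expect_error(normalise_volume(zero), "zero-energy")
  # peak option
  p <- normalise_volume(w, 0.5, method = "peak")
  expect_equal(max(abs(p$samples)), 0.5, tolerance = 1e-12)
})

test_that("WAV files round-trip samples and carry a correct header", {
  w <- synthesize_impact(material_spec("x", mode_params(0.5, 440, 3)), 8000)
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(normalise_volume(w, 0.1), path)
  con <- file(path, "rb")
  on.exit(close(con))
  expect_identical(readChar(con, 4), "RIFF")
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  expect_identical(readChar(con, 8), "WAVEfmt ")
  invisible(readBin(con, "integer", 3, 2, endian = "little"))  # chunk sz lo/hi, fmt, ch
  invisible(readBin(con, "integer", 1, 2, endian = "little"))
  expect_identical(readBin(con, "integer", 1, 4, endian = "little"), 8000L)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  invisible(readBin(con, "integer", 2, 2, endian = "little"))
  expect_identical(readChar(con, 4), "data")
  nbytes <- readBin(con, "integer", 1, 4, endian = "little")
  expect_identical(nbytes, 16000L)
  samples <- readBin(con, "integer", 8000, 2, endian = "little")
  target <- as.integer(round(pmax(pmin(normalise_volume(w, 0.1)$samples, 1), -1) * 32767))
  expect_identical(samples, target)
})
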