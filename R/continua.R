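#' CIELAB colour
#'
#' A point in CIELAB colour space. Lightness `L` must lie in \[0, 100\]; the
#' opponent coordinates `a` (green--red) and `b` (blue--yellow) are unbounded
#' but must be finite.
#'
#' @param L Lightness, in \[0, 100\].
#' @param a Green--red opponent coordinate.
#' @param b Blue--yellow opponent coordinate.
#' @return A named numeric vector of class `lab_colour`.
#' @examples
#' lab_colour(73.03, -19.98, 37.84)
#' @export
lab_colour <- function(L, a, b) {
  if (!all(is.finite(c(L, a, b)))) stop_invalid("CIELAB coordinates must be finite")
  if (L < 0 || L > 100) stop_invalid("L must lie in [0, 100]")
  structure(c(L = L, a = a, b = b), class = "lab_colour")
}

#' Linearly interpolate a colour continuum in CIELAB space
#'
#' Builds an `n`-step continuum from endpoint `A` to endpoint `B`, with every
#' coordinate an affine function of step index (equal spacing). Because CIELAB
#' is approximately perceptually uniform, equal coordinate steps give an
#' approximately perceptually smooth gradient.
#'
#' @param A,B `lab_colour` endpoints (step 1 is `A`, step `n` is `B`).
#' @param n Number of steps, endpoints included; must be >= 2.
#' @param label_A,label_B Category names for the two ends (e.g. "blue", "green").
#' @return A tibble of class `colour_continuum` with columns `step`, `L`, `a`,
#'   `b` and attributes `label_A`, `label_B`, `n_steps`.
#' @examples
#' cc <- interpolate_lab(lab_colour(73.03, -19.98, 37.84),
#'                       lab_colour(87.24, -62.94, 41.00),
#'                       n = 50, label_A = "blue", label_B = "green")
#' cc[c(1, 26, 50), ]
#' @export
interpolate_lab <- function(A, B, n, label_A = "A", label_B = "B") {
  stopifnot(inherits(A, "lab_colour"), inherits(B, "lab_colour"))
  if (!is.numeric(n) || n < 2) stop_invalid("n must be at least 2")
  n <- as.integer(n)
  f <- (seq_len(n) - 1) / (n - 1)
  out <- tibble::tibble(
    step = seq_len(n),
    L = A[["L"]] + (B[["L"]] - A[["L"]]) * f,
    a = A[["a"]] + (B[["a"]] - A[["a"]]) * f,
    b = A[["b"]] + (B[["b"]] - A[["b"]]) * f
  )
  structure(out,
    class = c("colour_continuum", class(out)),
    label_A = label_A, label_B = label_B, n_steps = n
  )
}

#' Convert a CIELAB colour to sRGB
#'
#' Standard CIELAB -> XYZ (D65 white) -> linear RGB -> sRGB (piecewise gamma)
#' transform. Out-of-gamut channels are clipped to \[0, 255\] with a warning;
#' clipping is deliberately not an error because downstream staircase logic
#' depends only on step indices, never on rendered colour.
#'
#' @param c A `lab_colour` (or numeric vector `c(L, a, b)`).
#' @return A list with `rgb` (integer triple in 0..255) and `hex` (e.g. "#aabbcc").
#' @examples
#' lab_to_srgb(lab_colour(100, 0, 0))$hex  # white
#' @export
lab_to_srgb <- function(c) {
  L <- c[[1]]; a <- c[[2]]; b <- c[[3]]
  # D65 reference white (2 degree observer), normalised Y = 1
  wn <- c(X = 0.95047, Y = 1.0, Z = 1.08883)
  fy <- (L + 16) / 116
  fx <- fy + a / 500
  fz <- fy - b / 200
  finv <- function(t) ifelse(t^3 > 216 / 24389, t^3, (116 * t - 16) * 27 / 24389)
  xyz <- wn * c(finv(fx), finv(fy), finv(fz))
  m <- matrix(c(
    3.2404542, -1.5371385, -0.4985314,
    -0.9692660, 1.8760108, 0.0415560,
    0.0556434, -0.2040259, 1.0572252
  ), 3, 3, byrow = TRUE)
  lin <- as.numeric(m %*% xyz)
  gamma <- function(u) ifelse(u <= 0.0031308, 12.92 * u, 1.055 * u^(1 / 2.4) - 0.055)
  srgb <- gamma(lin)
  if (any(srgb < -1e-6 | srgb > 1 + 1e-6)) {
    warning("CIELAB colour out of sRGB gamut; channels clipped", call. = FALSE)
  }
  rgb255 <- as.integer(round(clamp(srgb, 0, 1) * 255))
  list(rgb = rgb255, hex = sprintf("#%02x%02x%02x", rgb255[1], rgb255[2], rgb255[3]))
}

#' Modal parameters of an impact-sound resonance
#'
#' @param amplitude Linear gain, >= 0.
#' @param frequency Centre frequency in Hz, > 0.
#' @param decay Exponential decay rate in 1/s, >= 0.
#' @return A one-row tibble with the three parameters.
#' @export
mode_params <- function(amplitude, frequency, decay) {
  if (amplitude < 0) stop_invalid("amplitude must be >= 0")
  if (frequency <= 0) stop_invalid("frequency must be > 0")
  if (decay < 0) stop_invalid("decay must be >= 0")
  tibble::tibble(amplitude = amplitude, frequency = frequency, decay = decay)
}

#' Material specification for modal sound synthesis
#'
#' A material is a bank of resonant modes, each with an amplitude, centre
#' frequency (Hz) and exponential decay rate (1/s), rendered over a fixed
#' 1-second duration.
#'
#' @param label Category name as presented to listeners (e.g. "wood", "metal").
#' @param modes A tibble/data frame with columns `amplitude`, `frequency`,
#'   `decay` (one row per mode, at least one row).
#' @param duration Sound duration in seconds; fixed at 1.
#' @return A list of class `material_spec`.
#' @export
material_spec <- function(label, modes, duration = 1.0) {
  modes <- tibble::as_tibble(modes)
  stopifnot(all(c("amplitude", "frequency", "decay") %in% names(modes)))
  if (nrow(modes) < 1) stop_invalid("a material needs at least one mode")
  if (any(modes$amplitude < 0) || any(modes$frequency <= 0) || any(modes$decay < 0)) {
    stop_invalid("invalid modal parameters")
  }
  if (!isTRUE(all.equal(duration, 1.0))) stop_invalid("duration is fixed at 1 s")
  structure(list(label = label, modes = modes, duration = duration),
    class = "material_spec"
  )
}

#' Linearly interpolate a material sound continuum
#'
#' Pairs the modes of `A` and `B` in ascending-frequency order (a deterministic
#' pairing that preserves spectral ordering) and interpolates each paired
#' mode's amplitude, frequency and decay affinely over `n` equally spaced
#' steps, endpoints included.
#'
#' @param A,B `material_spec` endpoints with equal mode counts.
#' @param n Number of steps including both endpoints (default 10); >= 2.
#' @return A list of class `sound_continuum`: fields `label_A`, `label_B`,
#'   `n_steps`, and `steps`, a list of `n` `material_spec` objects.
#' @export
interpolate_modal <- function(A, B, n = 10) {
  stopifnot(inherits(A, "material_spec"), inherits(B, "material_spec"))
  if (!is.numeric(n) || n < 2) stop_invalid("n must be at least 2")
  if (nrow(A$modes) != nrow(B$modes)) {
    stop_invalid("materials must have equal mode counts for interpolation")
  }
  n <- as.integer(n)
  ma <- A$modes[order(A$modes$frequency), ]
  mb <- B$modes[order(B$modes$frequency), ]
  steps <- lapply(seq_len(n), function(s) {
    f <- (s - 1) / (n - 1)
    material_spec(
      label = if (s <= n / 2) A$label else B$label,
      modes = tibble::tibble(
        amplitude = ma$amplitude + (mb$amplitude - ma$amplitude) * f,
        frequency = ma$frequency + (mb$frequency - ma$frequency) * f,
        decay = ma$decay + (mb$decay - ma$decay) * f
      )
    )
  })
  # endpoints must reproduce the (frequency-sorted) inputs exactly
  steps[[1]]$modes <- ma
  steps[[n]]$modes <- mb
  structure(list(label_A = A$label, label_B = B$label, n_steps = n, steps = steps),
    class = "sound_continuum"
  )
}

#' Synthesize an impact sound from modal parameters
#'
#' Additive synthesis of exponentially damped sinusoids:
#' `x(t) = sum_i a_i exp(-d_i t) sin(2 pi f_i t)` for `t` in \[0, 1 s). The
#' result is peak-limited to \[-1, 1\] by rescaling when the raw peak exceeds 1.
#'
#' @param m A `material_spec`.
#' @param sample_rate Sampling rate in Hz; must exceed twice the highest mode
#'   frequency (Nyquist). Default 44100.
#' @return A list of class `waveform` with `samples` (numeric vector) and
#'   `sample_rate`.
#' @export
synthesize_impact <- function(m, sample_rate = 44100) {
  stopifnot(inherits(m, "material_spec"))
  if (sample_rate <= 2 * max(m$modes$frequency)) {
    stop_invalid("sample_rate must exceed twice the highest mode frequency")
  }
  n <- round(m$duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  x <- numeric(n)
  for (i in seq_len(nrow(m$modes))) {
    x <- x + m$modes$amplitude[i] * exp(-m$modes$decay[i] * t) *
      sin(2 * pi * m$modes$frequency[i] * t)
  }
  peak <- max(abs(x))
  if (peak > 1) x <- x / peak
  structure(list(samples = x, sample_rate = sample_rate), class = "waveform")
}

#' Normalise waveform volume
#'
#' Rescales a waveform to a target RMS (default) or target peak amplitude,
#' preserving its shape up to a positive scalar. RMS is the default reading of
#' "volume"; a peak option is provided for completeness.
#'
#' @param w A `waveform`.
#' @param target Target RMS (or peak) amplitude, > 0. Default 0.1 RMS.
#' @param method `"rms"` or `"peak"`.
#' @return The rescaled `waveform`.
#' @export
normalise_volume <- function(w, target = 0.1, method = c("rms", "peak")) {
  stopifnot(inherits(w, "waveform"))
  method <- match.arg(method)
  level <- switch(method,
    rms = sqrt(mean(w$samples^2)),
    peak = max(abs(w$samples))
  )
  if (level == 0) stop_invalid("cannot normalise a zero-energy waveform")
  w$samples <- w$samples * (target / level)
  w
}

#' Write a waveform to a 16-bit PCM WAV file
#'
#' Minimal single-channel RIFF/WAVE writer. Samples are clipped to \[-1, 1\]
#' and quantised to signed 16-bit integers.
#'
#' @param w A `waveform`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path) {
  stopifnot(inherits(w, "waveform"))
  samples <- as.integer(round(clamp(w$samples, -1, 1) * 32767))
  sr <- as.integer(w$sample_rate)
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * length(samples)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")          # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(sr, con, size = 4, endian = "little")
  writeBin(sr * 2L, con, size = 4, endian = "little")      # byte rate
  writeBin(2L, con, size = 2, endian = "little")           # block align
  writeBin(16L, con, size = 2, endian = "little")          # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(samples, con, size = 2, endian = "little")
  invisible(path)
}

#' Default CIELAB continuum endpoints
#'
#' The two calibrated colour continua used by the first experiment design
#' (cool: blue-to-green; warm: yellow-to-orange) and the
#' lightness-equalised, perceptually proximate pair used by the second.
#'
#' @return A named list of lists with `A`, `B` (`lab_colour`) and labels.
#' @export
default_colour_endpoints <- function() {
  list(
    cool = list(
      A = lab_colour(73.03, -19.98, 37.84), label_A = "blue",
      B = lab_colour(87.24, -62.94, 41.00), label_B = "green"
    ),
    warm = list(
      A = lab_colour(88.29, -0.98, 69.51), label_A = "yellow",
      B = lab_colour(68.55, 40.91, 49.37), label_B = "orange"
    ),
    proximate = list(
      A = lab_colour(73, -36.31, -13.94), label_A = "blue",
      B = lab_colour(73, -54.46, 13.65), label_B = "green"
    )
  )
}

#' Load the packaged synthetic material definitions
#'
#' Modal parameter banks for wood, glass, cardboard and metal. These are
#' synthetic placeholder parameter sets (10 modes per material) shaped to give
#' plausible bright/damped spectra; every interpolation and synthesis contract
#' in the package holds for any parameter values.
#'
#' @return A named list of `material_spec` objects.
#' @export
default_materials <- function() {
  path <- system.file("extdata", "synthetic_materials.json", package = "refprodsim")
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(m) {
    material_spec(m$label, tibble::as_tibble(m$modes))
  })
}

#' Export a colour continuum manifest
#'
#' Writes one row per step with the CIELAB coordinates and the rendered sRGB
#' hex string. Columns: continuum, step, L, a, b, hex.
#'
#' @param continua Named list of `colour_continuum` objects.
#' @param path Output CSV path.
#' @return The manifest tibble, invisibly.
#' @export
write_colour_manifest <- function(continua, path) {
  rows <- purrr::imap(continua, function(cc, nm) {
    hex <- vapply(seq_len(nrow(cc)), function(i) {
      suppressWarnings(lab_to_srgb(c(cc$L[i], cc$a[i], cc$b[i]))$hex)
    }, character(1))
    tibble::tibble(continuum = nm, step = cc$step, L = cc$L, a = cc$a, b = cc$b, hex = hex)
  })
  manifest <- dplyr::bind_rows(rows)
  write.csv(manifest, path, row.names = FALSE)
  invisible(manifest)
}
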