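#' Specify a dynamic moving-ripple sound
#'
#' A moving ripple is a broadband carrier bank whose spectral envelope drifts
#' over time: at log-frequency position `g = log2(f / f0)` and time `t` the
#' envelope is
#' `s(g, t) = D0 + D * cos(2 * pi * (omega * t + Omega * g) + psi)`,
#' with ripple velocity `omega` (cycles/s), spectral density `Omega`
#' (cycles/octave), modulation depth `D` around base offset `D0`, and ripple
#' phase `psi`.
#'
#' @param omega Ripple velocity, cycles/s.
#' @param Omega Spectral density, cycles/octave.
#' @param duration Duration in seconds.
#' @param f0,f_hi Low/high carrier band edges, Hz.
#' @param density Carrier sinusoids per octave.
#' @param depth Modulation depth D.
#' @param base Base offset D0 (must be >= depth so the envelope stays
#'   non-negative).
#' @param phase Ripple phase psi, radians.
#' @param seed Integer seed for the random carrier phases.
#' @return A `ripple_spec` list.
#' @export
ripple_spec <- function(omega, Omega = 1, duration = 1, f0 = 200, f_hi = 1600,
                        density = 20, depth = 0.9, base = 1, phase = 0,
                        seed = 1L) {
  assert_scalar_num(omega, "omega")
  assert_scalar_num(duration, "duration", min = 1e-6)
  if (f0 <= 0 || f_hi <= f0) abort("need f_hi > f0 > 0")
  if (density < 1) abort("`density` must be >= 1")
  if (depth < 0 || depth > base) abort("need 0 <= depth <= base")
  structure(
    list(omega = omega, Omega = Omega, duration = duration, f0 = f0,
         f_hi = f_hi, density = density, depth = depth, base = base,
         phase = phase, seed = as.integer(seed)),
    class = "ripple_spec"
  )
}

#' Synthesize a moving-ripple waveform
#'
#' Superimposes `density` log-spaced sinusoidal carriers per octave between
#' `f0` and `f_hi`, each with a seeded random phase and amplitude-modulated by
#' the ripple envelope `s(g, t)`. The result is peak-normalized.
#'
#' @param spec A [ripple_spec()].
#' @param sample_rate Sampling rate in Hz; must exceed twice the highest
#'   carrier frequency.
#' @param peak Peak amplitude after normalization (default -3 dBFS).
#' @return Numeric waveform with attributes `sample_rate` and `spec`.
#' @export
synthesize_ripple <- function(spec, sample_rate = 16000, peak = 10^(-3 / 20)) {
  stopifnot(inherits(spec, "ripple_spec"))
  if (sample_rate <= 2 * spec$f_hi) {
    abort("`sample_rate` must exceed twice the highest carrier frequency")
  }
  n_oct <- log2(spec$f_hi / spec$f0)
  n_car <- ceiling(spec$density * n_oct)
  g <- seq(0, n_oct, length.out = n_car)       # log2 positions incl. both edges
  freqs <- spec$f0 * 2^g
  phases <- with_seed_if(spec$seed, runif(n_car, 0, 2 * pi))
  t <- seq(0, spec$duration - 1 / sample_rate, by = 1 / sample_rate)
  wave <- numeric(length(t))
  for (i in seq_len(n_car)) {
    env <- spec$base + spec$depth *
      cos(2 * pi * (spec$omega * t + spec$Omega * g[i]) + spec$phase)
    wave <- wave + env * sin(2 * pi * freqs[i] * t + phases[i])
  }
  m <- max(abs(wave))
  if (m > 0) wave <- wave * (peak / m)
  attr(wave, "sample_rate") <- sample_rate
  attr(wave, "spec") <- spec
  wave
}

#' Write a mono waveform as 16-bit PCM WAV
#'
#' Minimal RIFF/WAVE writer for exporting synthesized stimuli; samples are
#' clipped to \[-1, 1\] and quantized to 16 bits.
#'
#' @param wave Numeric vector in \[-1, 1\] (attribute `sample_rate` used if
#'   `sample_rate` is missing).
#' @param path Output file path.
#' @param sample_rate Sampling rate in Hz.
#' @return `path`, invisibly.
#' @export
write_wav <- function(wave, path, sample_rate = attr(wave, "sample_rate")) {
  if (is.null(sample_rate)) abort("`sample_rate` is required")
  pcm <- as.integer(round(pmax(-1, pmin(1, as.numeric(wave))) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")   # block align
  writeBin(16L, con, size = 2, endian = "little")  # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV written by [write_wav()]
#'
#' @param path File path.
#' @return Numeric waveform with attribute `sample_rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4)
  if (!identical(hdr, "RIFF")) abort("not a RIFF file")
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  if (!identical(readChar(con, 8), "WAVEfmt ")) abort("unsupported WAV layout")
  fmt_len <- readBin(con, "integer", 1, size = 4, endian = "little")
  fmt <- readBin(con, "integer", fmt_len / 2, size = 2, endian = "little")
  lo <- fmt[3] + if (fmt[3] < 0) 65536 else 0  # undo signed 16-bit read
  rate <- lo + 65536 * fmt[4]
  if (!identical(readChar(con, 4), "data")) abort("unsupported WAV layout")
  nbytes <- readBin(con, "integer", 1, size = 4, endian = "little")
  pcm <- readBin(con, "integer", nbytes / 2, size = 2, signed = TRUE,
                 endian = "little")
  wave <- pcm / 32767
  attr(wave, "sample_rate") <- rate
  wave
}
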