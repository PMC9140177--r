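#' Construct a waveform object
#'
#' A waveform is a mono PCM amplitude sequence with a sampling rate. All
#' stimulus audio in the package flows through this container.
#'
#' @param samples Numeric vector of amplitudes (dimensionless, nominally in
#'   \eqn{[-1, 1]}).
#' @param rate Sampling rate in Hz (must be positive).
#' @return An object of class `waveform` with elements `samples` and `rate`.
#' @examples
#' w <- waveform(sin(2 * pi * 440 * seq(0, 0.1, by = 1 / 16000)), 16000)
#' duration_ms(w)
#' @export
waveform <- function(samples, rate) {
  if (is.matrix(samples) && ncol(samples) > 1L) {
    stop("non-mono input: expected a single channel, got ", ncol(samples))
  }
  samples <- as.numeric(samples)
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("rate must be a single positive number")
  }
  structure(list(samples = samples, rate = rate), class = "waveform")
}

#' Duration of a waveform in milliseconds
#'
#' @param w A `waveform`.
#' @return Duration in ms (`1000 * length(samples) / rate`).
#' @export
duration_ms <- function(w) {
  stopifnot(inherits(w, "waveform"))
  1000 * length(w$samples) / w$rate
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform: %.1f ms at %d Hz, peak %.3f>\n",
              duration_ms(x), as.integer(x$rate),
              if (length(x$samples)) max(abs(x$samples)) else 0))
  invisible(x)
}

#' Read a mono 16-bit PCM WAV file
#'
#' Reads RIFF/WAVE files with 16-bit integer PCM samples. Stereo or other
#' sample formats are rejected. Samples are scaled to \eqn{[-1, 1)}.
#'
#' @param path Path to a `.wav` file.
#' @return A [waveform()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  rate <- NULL; bits <- NULL; channels <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", size / 2, size = 2,
                     endian = "little", signed = FALSE)
      audio_format <- fmt[1]
      channels <- fmt[2]
      rate <- fmt[3] + 65536 * fmt[4]
      bits <- fmt[8]
      if (audio_format != 1L) stop("unsupported WAV encoding (not PCM)")
      if (bits != 16L) stop("unsupported WAV bit depth: ", bits)
      if (channels != 1L) stop("non-mono input: ", channels, " channels")
    } else if (identical(id, "data")) {
      samples <- readBin(con, "integer", size / 2, size = 2,
                         endian = "little", signed = TRUE)
      break
    } else {
      invisible(readBin(con, "raw", size))
    }
  }
  if (is.null(rate) || is.null(samples)) stop("malformed WAV file: ", path)
  waveform(samples / 32768, rate)
}

#' Write a waveform as a mono 16-bit PCM WAV file
#'
#' Amplitudes are clipped to \eqn{[-1, 1]} and quantized to 16 bits.
#'
#' @param w A [waveform()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path) {
  stopifnot(inherits(w, "waveform"))
  x <- pmax(pmin(w$samples, 1), -1)
  pcm <- as.integer(round(x * 32767))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(as.integer(16), con, size = 4, endian = "little")
  writeBin(as.integer(c(1, 1)), con, size = 2, endian = "little")   # PCM, mono
  writeBin(as.integer(w$rate), con, size = 4, endian = "little")
  writeBin(as.integer(w$rate * 2), con, size = 4, endian = "little") # byte rate
  writeBin(as.integer(c(2, 16)), con, size = 2, endian = "little")  # align, bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Specify segment-localized noise
#'
#' Describes an interval of a stimulus to be degraded by additive noise at a
#' stated signal-to-noise ratio, e.g. white noise over a stressed vowel.
#'
#' @param start_ms,end_ms Interval boundaries in ms from stimulus onset;
#'   `0 <= start_ms < end_ms`.
#' @param snr_db Signal-to-noise ratio in dB, measured as the ratio of signal
#'   power to noise power over the noised interval only.
#' @param kind Noise type tag; only `"white"` (Gaussian) is implemented.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(start_ms, end_ms, snr_db, kind = "white") {
  if (!is.numeric(start_ms) || !is.numeric(end_ms) || start_ms < 0 ||
      end_ms <= start_ms) {
    stop("need 0 <= start_ms < end_ms")
  }
  if (!identical(kind, "white")) stop("unsupported noise kind: ", kind)
  structure(list(start_ms = start_ms, end_ms = end_ms,
                 snr_db = snr_db, kind = kind),
            class = "noise_spec")
}

# Run expr with a private RNG stream; caller's RNG state is untouched.
with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Superimpose noise on a segment of a waveform
#'
#' Adds white Gaussian noise to the interval given by `spec`, scaled so that
#' the ratio of segment signal power to noise power equals `spec$snr_db`
#' (i.e. `10*log10(P_signal/P_noise) == snr_db` over the interval). Samples
#' outside the interval are returned bit-identically.
#'
#' @param w A [waveform()].
#' @param spec A [noise_spec()]; the interval must lie inside the stimulus.
#' @param seed Integer seed; the same seed yields bit-identical output.
#' @return A new [waveform()].
#' @export
add_segment_noise <- function(w, spec, seed) {
  stopifnot(inherits(w, "waveform"), inherits(spec, "noise_spec"))
  dur <- duration_ms(w)
  if (spec$end_ms > dur + 1e-9) {
    stop("noise interval [", spec$start_ms, ", ", spec$end_ms,
         "] ms exceeds stimulus duration ", round(dur, 3), " ms")
  }
  i0 <- floor(spec$start_ms * w$rate / 1000) + 1L
  i1 <- ceiling(spec$end_ms * w$rate / 1000)
  i1 <- min(i1, length(w$samples))
  if (i1 < i0) stop("empty noise interval")
  seg <- w$samples[i0:i1]
  p_sig <- mean(seg^2)
  noise <- with_local_seed(seed, stats::rnorm(length(seg)))
  # target noise power: P_sig / 10^(snr/10); scale the unit-variance draw
  p_noise_target <- p_sig / 10^(spec$snr_db / 10)
  noise <- noise * sqrt(p_noise_target / mean(noise^2))
  out <- w$samples
  out[i0:i1] <- seg + noise
  waveform(out, w$rate)
}
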