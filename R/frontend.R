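#' Front-end configuration
#'
#' Constants of the acoustic front end. The 25 ms window / 10 ms step /
#' 39-dimensional layout (13 static cepstra plus first and second time
#' derivatives) is fixed by the model; the remaining knobs are conventional
#' MFCC choices and overridable.
#'
#' @param window_ms Analysis window length in ms.
#' @param step_ms Frame step in ms.
#' @param n_cep Number of static cepstral coefficients kept (term 0 carries
#'   energy).
#' @param n_mel Number of triangular Mel filters.
#' @param preemph Pre-emphasis coefficient.
#' @param delta_half_window Half-window (in frames) of the delta regression.
#' @return A list of class `frontend_config`.
#' @export
frontend_config <- function(window_ms = 25, step_ms = 10, n_cep = 13,
                            n_mel = 26, preemph = 0.97,
                            delta_half_window = 2) {
  structure(list(window_ms = window_ms, step_ms = step_ms, n_cep = n_cep,
                 n_mel = n_mel, preemph = preemph,
                 delta_half_window = delta_half_window),
            class = "frontend_config")
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# Triangular Mel filterbank as an (n_fft/2 + 1) x n_mel matrix.
mel_filterbank <- function(n_mel, n_fft, rate) {
  n_bins <- n_fft / 2 + 1
  freqs <- (seq_len(n_bins) - 1) * rate / n_fft
  edges <- mel_to_hz(seq(hz_to_mel(0), hz_to_mel(rate / 2),
                         length.out = n_mel + 2))
  fb <- matrix(0, n_bins, n_mel)
  for (m in seq_len(n_mel)) {
    lo <- edges[m]; ce <- edges[m + 1]; hi <- edges[m + 2]
    up <- (freqs - lo) / (ce - lo)
    dn <- (hi - freqs) / (hi - ce)
    fb[, m] <- pmax(0, pmin(up, dn))
  }
  fb
}

# Orthonormal DCT-II basis, n_out x n_in. Row 1 is the constant basis
# vector, so a uniform offset of the inputs moves only coefficient 0.
dct_basis <- function(n_out, n_in) {
  k <- seq_len(n_out) - 1
  n <- seq_len(n_in) - 1
  B <- cos(outer(k, n + 0.5) * pi / n_in) * sqrt(2 / n_in)
  B[1, ] <- B[1, ] / sqrt(2)
  B
}

#' Regression-based time derivatives of cepstral trajectories
#'
#' Appends first and second time derivatives computed by least-squares
#' regression over `+-half_window` frames, with replication padding at the
#' edges. With a single frame all derivatives are zero.
#'
#' @param statics A `T x k` matrix of per-frame static coefficients.
#' @param half_window Regression half-window in frames (>= 1).
#' @return A `T x 2k` matrix: first derivatives, then second derivatives.
#' @export
compute_deltas <- function(statics, half_window = 2) {
  statics <- as.matrix(statics)
  if (half_window < 1) stop("half_window must be >= 1")
  T_ <- nrow(statics)
  denom <- 2 * sum(seq_len(half_window)^2)
  delta_of <- function(m) {
    d <- matrix(0, nrow(m), ncol(m))
    for (k in seq_len(half_window)) {
      fwd <- m[pmin(seq_len(T_) + k, T_), , drop = FALSE]
      bwd <- m[pmax(seq_len(T_) - k, 1L), , drop = FALSE]
      d <- d + k * (fwd - bwd)
    }
    d / denom
  }
  d1 <- delta_of(statics)
  d2 <- delta_of(d1)
  cbind(d1, d2)
}

#' Extract the 39-dimensional feature trajectory of a waveform
#'
#' Converts audio to per-frame feature vectors: 13 Mel-frequency cepstral
#' coefficients over a 25 ms Hamming window every 10 ms, plus their first and
#' second regression derivatives. Frames are centered so that frame `t`
#' covers `[(t-1)*step, t*step)` ms (the signal is reflect-padded at the
#' edges), giving `floor(duration/step)` frames.
#'
#' @param w A [waveform()]; `rate >= 8000` Hz and at least one window long.
#' @param config A [frontend_config()].
#' @return An object of class `feature_trajectory`: list with `frames`
#'   (`T x 39` matrix), `frame_step_ms`, `window_ms`, `t0_ms` (time of the
#'   first frame center) and `rate`.
#' @export
extract_features <- function(w, config = frontend_config()) {
  stopifnot(inherits(w, "waveform"))
  if (w$rate < 8000) stop("sampling rate must be >= 8000 Hz, got ", w$rate)
  win <- round(config$window_ms * w$rate / 1000)
  hop <- round(config$step_ms * w$rate / 1000)
  n <- length(w$samples)
  if (n < win) {
    stop("waveform (", n, " samples) shorter than one analysis window (",
         win, " samples)")
  }
  x <- w$samples
  # pre-emphasis
  x <- c(x[1] * (1 - config$preemph), x[-1] - config$preemph * x[-n])
  # reflect-pad so that frame t is centered at (t - 1) * step + step/2
  pad <- (win - hop) %/% 2
  if (pad > 0) {
    x <- c(rev(x[2:(pad + 1)]), x, rev(x[(n - pad):(n - 1)]))
  }
  T_ <- n %/% hop
  n_fft <- 2^ceiling(log2(win))
  fb <- mel_filterbank(config$n_mel, n_fft, w$rate)
  B <- dct_basis(config$n_cep, config$n_mel)
  ham <- 0.54 - 0.46 * cos(2 * pi * (seq_len(win) - 1) / (win - 1))
  statics <- matrix(0, T_, config$n_cep)
  for (t in seq_len(T_)) {
    fr <- x[((t - 1) * hop + 1):((t - 1) * hop + win)] * ham
    spec <- abs(stats::fft(c(fr, numeric(n_fft - win))))^2
    melE <- drop(crossprod(fb, spec[seq_len(n_fft / 2 + 1)]))
    statics[t, ] <- drop(B %*% log(pmax(melE, .Machine$double.xmin)))
  }
  structure(list(frames = cbind(statics,
                                compute_deltas(statics,
                                               config$delta_half_window)),
                 frame_step_ms = config$step_ms,
                 window_ms = config$window_ms,
                 t0_ms = config$step_ms / 2,
                 rate = w$rate),
            class = "feature_trajectory")
}

#' @export
print.feature_trajectory <- function(x, ...) {
  cat(sprintf("<feature_trajectory: %d frames x %d dims, step %g ms>\n",
              nrow(x$frames), ncol(x$frames), x$frame_step_ms))
  invisible(x)
}

#' Number of frames in a feature trajectory
#' @param ft A `feature_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(ft) nrow(ft$frames)

#' Write a feature trajectory to CSV
#'
#' One row per frame: `time_ms` (frame center) followed by the 39 feature
#' components `c01..c13`, `d01..d13`, `dd01..dd13`.
#'
#' @param ft A `feature_trajectory`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(ft, path) {
  T_ <- nrow(ft$frames)
  df <- data.frame(time_ms = ft$t0_ms + (seq_len(T_) - 1) * ft$frame_step_ms)
  m <- as.data.frame(ft$frames)
  names(m) <- c(sprintf("c%02d", 1:13), sprintf("d%02d", 1:13),
                sprintf("dd%02d", 1:13))
  utils::write.csv(cbind(df, m), path, row.names = FALSE)
  invisible(path)
}
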