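#' Intracranial EEG recording
#'
#' Channels x samples matrix in microvolts with its sampling rate, seizure
#' onset sample, pre-ictal baseline window, and the mapping from channel
#' labels to electrode contacts. Recordings in this study are referential
#' (subgaleal reference) and acquired at 3052 Hz.
#'
#' @param data Numeric channels x samples matrix (microvolts).
#' @param fs_hz Sampling rate in Hz.
#' @param channel_labels Character vector, one label per row of `data`; each
#'   must match exactly one electrode contact.
#' @param onset_sample Sample index (1-based) of electrographic seizure onset.
#' @param baseline_window Integer `c(start, end)` sample indices of the
#'   pre-ictal baseline; must end before `onset_sample`.
#' @param reference_label Label of the reference electrode.
#' @return An object of class `iceeg_recording`.
#' @export
iceeg_recording <- function(data, fs_hz, channel_labels,
                            onset_sample, baseline_window,
                            reference_label = "subgaleal") {
  data <- as.matrix(data)
  if (length(channel_labels) != nrow(data)) {
    stop("one channel label per data row required", call. = FALSE)
  }
  if (anyDuplicated(channel_labels)) {
    stop("channel labels must be unique", call. = FALSE)
  }
  if (!all(is.finite(data))) stop("recording contains NaN/Inf", call. = FALSE)
  baseline_window <- as.integer(baseline_window)
  onset_sample <- as.integer(onset_sample)
  if (length(baseline_window) != 2L || baseline_window[1] < 1L ||
      baseline_window[2] < baseline_window[1]) {
    stop("invalid baseline_window", call. = FALSE)
  }
  if (baseline_window[2] >= onset_sample) {
    stop("baseline_window must be entirely pre-onset", call. = FALSE)
  }
  structure(
    list(data = data, fs_hz = fs_hz,
         channel_labels = as.character(channel_labels),
         onset_sample = onset_sample, baseline_window = baseline_window,
         reference_label = reference_label),
    class = "iceeg_recording")
}

#' @export
print.iceeg_recording <- function(x, ...) {
  cat(sprintf("<iceeg_recording> %d channels x %d samples @ %.6g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs_hz, ncol(x$data) / x$fs_hz))
  cat(sprintf("  onset at %.2f s; baseline %.2f-%.2f s; reference %s\n",
              x$onset_sample / x$fs_hz, x$baseline_window[1] / x$fs_hz,
              x$baseline_window[2] / x$fs_hz, x$reference_label))
  invisible(x)
}

#' Anti-alias low-pass filter and resample
#'
#' Low-pass filters each channel below `cutoff_hz` (zero-phase FIR, so onset
#' latency is not shifted) and resamples to `target_fs` by polyphase
#' rational-ratio resampling. Onset and baseline indices are re-indexed
#' proportionally. The study pipeline filters to <255 Hz before resampling
#' 3052 Hz recordings to 512 Hz.
#'
#' @param rec An `iceeg_recording`.
#' @param target_fs Output sampling rate in Hz (must be below `rec$fs_hz`).
#' @param cutoff_hz Anti-alias cutoff in Hz.
#' @param fir_order FIR filter order for the anti-alias low-pass.
#' @return A resampled `iceeg_recording`.
#' @export
antialias_resample <- function(rec, target_fs = 512, cutoff_hz = 255,
                               fir_order = 400L) {
  stopifnot(inherits(rec, "iceeg_recording"))
  if (target_fs >= rec$fs_hz) {
    stop("target_fs must be below the recording sampling rate", call. = FALSE)
  }
  if (cutoff_hz >= rec$fs_hz / 2) {
    stop("cutoff_hz must be below Nyquist", call. = FALSE)
  }
  h <- signal::fir1(fir_order, 2 * cutoff_hz / rec$fs_hz, type = "low")
  h <- h / sum(h)  # unit DC gain
  pq <- rational_approx(target_fs / rec$fs_hz)
  out <- t(apply(rec$data, 1, function(x) {
    x <- filtfilt_refl(h, 1, x)
    resample_fft(x, pq[["p"]], pq[["q"]])
  }))
  ratio <- target_fs / rec$fs_hz
  iceeg_recording(out, target_fs, rec$channel_labels,
                  onset_sample = max(1L, round(rec$onset_sample * ratio)),
                  baseline_window = pmax(1L, round(rec$baseline_window * ratio)),
                  reference_label = rec$reference_label)
}

# Zero-phase filtering: odd (point-symmetric) reflection padding plus
# steady-state initial conditions at the edge level, so neither constant
# offsets nor oscillations at the record edges leave start-up transients.
filtfilt_refl <- function(b, a, x) {
  b <- as.numeric(b); a <- as.numeric(a)
  n <- length(x)
  # pad well beyond the coefficient count: narrow-band IIR transients
  # (e.g. high-Q notches) ring for hundreds of samples
  nfact <- min(max(3L * (max(length(b), length(a)) - 1L), 512L), n - 1L)
  ext <- if (nfact > 0L) {
    c(2 * x[1] - x[seq(nfact + 1L, 2L)], x,
      2 * x[n] - x[seq(n - 1L, n - nfact)])
  } else x
  G <- sum(b) / sum(a)  # DC gain
  run <- function(v) {
    as.numeric(signal::filter(b, a, v,
                              init = rep(G * v[1], length(a) - 1L),
                              init.x = rep(v[1], length(b) - 1L)))
  }
  y <- run(ext)
  y <- rev(run(rev(y)))
  y[nfact + seq_len(n)]
}

# Exact band-limited rational-ratio resampling via the FFT. The record is
# odd-reflection padded by q input samples per side (where long enough) so
# the periodicity junction lies in discarded territory, and a linear ramp
# between the padded record's endpoints is removed first so the junction is
# value-continuous.
resample_fft <- function(x, p, q) {
  g <- gcd_int(p, q)
  p <- p / g; q <- q / g
  n <- length(x)
  pad <- if (n - 1L >= q) as.integer(q) else 0L
  xx <- if (pad > 0L) {
    c(2 * x[1] - x[seq(pad + 1L, 2L)], x, 2 * x[n] - x[seq(n - 1L, n - pad)])
  } else x
  L0 <- length(xx)
  ramp0 <- xx[1]
  slope <- (xx[L0] - xx[1]) / (L0 - 1)
  d <- xx - (ramp0 + slope * (seq_len(L0) - 1))
  L <- as.integer(q * ceiling(L0 / q))
  d <- c(d, numeric(L - L0))
  M <- as.integer(L * p / q)
  X <- stats::fft(d)
  Z <- complex(M)
  h <- min((M - 1L) %/% 2L, (L - 1L) %/% 2L)
  Z[1] <- X[1]
  if (h > 0L) {
    Z[2L:(h + 1L)] <- X[2L:(h + 1L)]
    Z[(M - h + 1L):M] <- X[(L - h + 1L):L]
  }
  y <- Re(stats::fft(Z, inverse = TRUE)) / L
  j <- seq_len(round(n * p / q)) + as.integer(pad * p / q)
  tj <- (j - 1) * q / p  # output sample times in input-sample units of xx
  y[j] + ramp0 + slope * tj
}

gcd_int <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  while (b != 0L) { t <- b; b <- a %% b; a <- t }
  a
}

# RBJ second-order notch biquad at f0 with quality factor Q.
notch_biquad <- function(f0, fs, Q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Notch filter at mains frequency and harmonics
#'
#' Applies zero-phase second-order notch filters at `base_hz` and every
#' integer harmonic strictly below Nyquist (60, 120, 180, 240 Hz at a 512 Hz
#' sampling rate).
#'
#' @param rec An `iceeg_recording`.
#' @param base_hz Mains frequency (60 Hz in North America).
#' @param Q Notch quality factor (centre frequency / -3 dB bandwidth). The
#'   default keeps the cascaded zero-phase response within 1 dB of unity
#'   outside +/- 2 Hz of each notch.
#' @return A filtered `iceeg_recording`.
#' @export
notch_filter <- function(rec, base_hz = 60, Q = 60) {
  stopifnot(inherits(rec, "iceeg_recording"))
  nyq <- rec$fs_hz / 2
  if (base_hz >= nyq) stop("base_hz must be below Nyquist", call. = FALSE)
  freqs <- seq(base_hz, nyq - 1e-9, by = base_hz)
  freqs <- freqs[freqs < nyq]
  data <- rec$data
  for (f0 in freqs) {
    bq <- notch_biquad(f0, rec$fs_hz, Q)
    data <- t(apply(data, 1, function(x) filtfilt_refl(bq$b, bq$a, x)))
  }
  rec$data <- data
  rec
}

#' Exclude channels with poor signal
#'
#' Removes flat channels (overall SD below `flat_eps`) and amplitude
#' outliers whose baseline-window SD exceeds `outlier_k` times the median
#' baseline SD across channels. The exclusion rule is a configurable
#' stand-in: clinical review uses expert judgement.
#'
#' @param rec An `iceeg_recording` with >= 2 channels.
#' @param flat_eps Flatness threshold (microvolts SD).
#' @param outlier_k Multiplier on the median baseline SD above which a
#'   channel is an amplitude outlier.
#' @return A list with elements `recording` (channels removed) and
#'   `excluded` (character vector of removed labels).
#' @export
exclude_bad_channels <- function(rec, flat_eps = 1e-6, outlier_k = 10) {
  stopifnot(inherits(rec, "iceeg_recording"))
  if (nrow(rec$data) < 2L) stop("need >= 2 channels", call. = FALSE)
  bw <- rec$baseline_window
  base_sd <- apply(rec$data[, bw[1]:bw[2], drop = FALSE], 1, stats::sd)
  all_sd <- apply(rec$data, 1, stats::sd)
  flat <- all_sd < flat_eps
  outlier <- base_sd > outlier_k * stats::median(base_sd)
  bad <- flat | outlier
  if (all(bad)) stop("all channels excluded", call. = FALSE)
  excluded <- rec$channel_labels[bad]
  rec$data <- rec$data[!bad, , drop = FALSE]
  rec$channel_labels <- rec$channel_labels[!bad]
  list(recording = rec, excluded = excluded)
}

#' Full preprocessing chain
#'
#' Fixed order: resample (with anti-alias low-pass) at the target rate, then
#' notch at the final sampling rate, then bad-channel exclusion.
#'
#' @inheritParams antialias_resample
#' @inheritParams notch_filter
#' @inheritParams exclude_bad_channels
#' @return As [exclude_bad_channels()].
#' @export
preprocess_recording <- function(rec, target_fs = 512, cutoff_hz = 255,
                                 base_hz = 60, Q = 60,
                                 flat_eps = 1e-6, outlier_k = 10) {
  rec <- antialias_resample(rec, target_fs, cutoff_hz)
  rec <- notch_filter(rec, base_hz, Q)
  exclude_bad_channels(rec, flat_eps, outlier_k)
}
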