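#' Zero-phase band-pass filter
#'
#' Applies a zero-phase band-pass to every channel. The gain is the
#' forward-backward magnitude response of an order-`order` analog Butterworth
#' band-pass prototype, applied in the frequency domain (exactly zero phase,
#' so directed-connectivity estimates are not lag-distorted). Signals are
#' mirror-padded by up to one second per side to suppress wrap-around edge
#' effects. With `lo = 0` the filter degenerates to a low-pass.
#'
#' The default effective order is deliberately steep: with a 45 Hz upper
#' edge the 50 Hz mains line sits just 5 Hz into the stop band, and a
#' forward-backward order-4 IIR Butterworth would pass roughly 38% of its
#' amplitude. Frequency-domain application is unconditionally stable at any
#' order, so a steep response costs nothing (high-order IIR band-pass
#' filters of this width are numerically unstable in practice).
#'
#' @param rec an [recording()] object.
#' @param lo,hi band edges in Hz; `0 <= lo < hi < fs/2`.
#' @param order effective Butterworth magnitude order (default 24).
#' @param notch optional mains frequency in Hz; a band-stop of width 2 Hz is
#'   applied around it.
#' @return the filtered recording (same length, same metadata).
#' @export
bandpass_filter <- function(rec, lo = 0.5, hi = 45, order = 24, notch = NULL) {
  assert_recording(rec)
  if (lo < 0 || lo >= hi) stop("need 0 <= lo < hi; got lo=", lo, " hi=", hi)
  if (hi >= rec$fs / 2)
    stop("upper edge hi=", hi, " Hz must be below Nyquist (", rec$fs / 2, " Hz)")
  gain <- function(f) {
    g <- if (lo > 0) {
      w <- ifelse(f > 0, (f^2 - lo * hi) / (f * (hi - lo)), Inf)
      1 / (1 + w^(2 * order))
    } else {
      1 / (1 + (f / hi)^(2 * order))
    }
    if (!is.null(notch)) {
      nlo <- notch - 1; nhi <- notch + 1
      wn <- ifelse(f > 0, (f^2 - nlo * nhi) / (f * (nhi - nlo)), Inf)
      g <- g * (1 - 1 / (1 + wn^(2 * order)))
    }
    g
  }
  rec$samples <- t(apply(rec$samples, 1L, fft_apply_gain, fs = rec$fs,
                         gain = gain))
  rec
}

# multiply the spectrum of x by gain(f) with mirror padding
fft_apply_gain <- function(x, fs, gain) {
  n <- length(x)
  pad <- min(n, as.integer(fs))
  xp <- c(rev(x[seq_len(pad)]), x, rev(x[n - seq_len(pad) + 1L]))
  np <- length(xp)
  f <- (seq_len(np) - 1L) / np * fs
  f <- pmin(f, fs - f)                 # fold to [0, fs/2]
  y <- Re(stats::fft(stats::fft(xp) * gain(f), inverse = TRUE)) / np
  y[pad + seq_len(n)]
}

#' Integer-factor decimation with anti-alias filtering
#'
#' Low-pass filters each channel (zero-phase Butterworth-magnitude response,
#' cutoff `0.45 * target_fs`, order 8) and keeps every `fs/target_fs`-th
#' sample.
#'
#' @param rec an [recording()] object.
#' @param target_fs target sampling rate; must divide `rec$fs` exactly.
#' @return the decimated recording.
#' @export
downsample <- function(rec, target_fs) {
  assert_recording(rec)
  ratio <- rec$fs / target_fs
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("target_fs=", target_fs, " is not an integer divisor of fs=", rec$fs)
  ratio <- as.integer(round(ratio))
  if (ratio == 1L) return(rec)
  fc <- 0.45 * target_fs
  rec$samples <- t(apply(rec$samples, 1L, fft_apply_gain, fs = rec$fs,
                         gain = function(f) 1 / (1 + (f / fc)^16)))
  rec$samples <- rec$samples[, seq(1L, ncol(rec$samples), by = ratio),
                             drop = FALSE]
  rec$fs <- target_fs
  rec
}

#' Common average re-reference of the EEG montage
#'
#' Subtracts the instantaneous mean across all EEG channels from every EEG
#' channel; ECG channels are untouched. Idempotent. Note that after this
#' operation the EEG block has rank one less than its channel count (the
#' per-sample EEG mean is exactly zero); see the methods vignette for the
#' consequence on joint MVAR fitting.
#'
#' @param rec an [recording()] object with at least one EEG channel.
#' @return the re-referenced recording.
#' @export
rereference_common_average <- function(rec) {
  assert_recording(rec)
  eeg <- rec$kinds == "EEG"
  if (!any(eeg)) stop("no EEG channels to re-reference")
  avg <- colMeans(rec$samples[eeg, , drop = FALSE])
  rec$samples[eeg, ] <- sweep(rec$samples[eeg, , drop = FALSE], 2L, avg)
  rec
}

#' Segment a recording into sliding analysis windows
#'
#' Fixed-length windows with fractional overlap; the hop is
#' `n_win * (1 - overlap)` samples and any trailing partial window is dropped
#' (MVAR fitting needs fixed-length segments).
#'
#' @param rec an [recording()] object.
#' @param window_ms window length in milliseconds (default 5000).
#' @param overlap fractional overlap in `[0, 1)` (default 0.5).
#' @return a list of `window_segment` objects (empty, with a warning, if the
#'   recording is shorter than one window).
#' @export
segment_windows <- function(rec, window_ms = 5000, overlap = 0.5) {
  assert_recording(rec)
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  n <- ncol(rec$samples)
  n_win <- as.integer(round(window_ms / 1000 * rec$fs))
  if (n < n_win) {
    warning("recording (", n, " samples) shorter than one window (", n_win,
            "); returning no windows")
    return(list())
  }
  hop <- as.integer(round(n_win * (1 - overlap)))
  if (hop < 1L) stop("overlap too large: hop would be < 1 sample")
  starts <- seq(0L, n - n_win, by = hop)
  lapply(starts, function(s0)
    structure(list(samples = rec$samples[, s0 + seq_len(n_win), drop = FALSE],
                   fs = rec$fs, start_s = s0 / rec$fs, stationary = NA,
                   labels = rec$labels, kinds = rec$kinds,
                   emotion = rec$emotion, subject_id = rec$subject_id),
              class = "window_segment"))
}

#' @export
print.window_segment <- function(x, ...) {
  cat(sprintf("<window_segment> %d ch x %d samples @ %g Hz, start %.2f s, stationary: %s\n",
              nrow(x$samples), ncol(x$samples), x$fs, x$start_s,
              as.character(x$stationary)))
  invisible(x)
}

#' Variance-ratio stationarity test for a window
#'
#' Splits each channel into two equal halves and compares their variances
#' with a two-sided F test (ratio of the larger to the smaller variance).
#' The window is flagged stationary when at least `channel_frac` of the
#' channels pass at level `alpha`. Zero-variance channels are reported as
#' failing with a degenerate-signal note.
#'
#' @param win a `window_segment` (at least 64 samples).
#' @param alpha per-channel significance level (default 0.05).
#' @param channel_frac fraction of channels that must pass (default 0.9).
#' @return a list with `stationary` (logical) and `table` (one row per
#'   channel: variance ratio, p value, pass flag, note).
#' @export
variance_ratio_stationarity <- function(win, alpha = 0.05,
                                        channel_frac = 0.9) {
  stopifnot(inherits(win, "window_segment"))
  n <- ncol(win$samples)
  if (n < 64L) stop("window too short for stationarity test (need >= 64 samples)")
  h <- n %/% 2L
  df <- h - 1L
  res <- lapply(seq_len(nrow(win$samples)), function(i) {
    x <- win$samples[i, ]
    v1 <- stats::var(x[seq_len(h)])
    v2 <- stats::var(x[(n - h + 1L):n])
    if (v1 <= 0 || v2 <= 0)
      return(data.frame(channel = win$labels[i], ratio = NA_real_,
                        p = 0, pass = FALSE, note = "degenerate (zero variance)"))
    ratio <- max(v1, v2) / min(v1, v2)
    p <- min(1, 2 * stats::pf(ratio, df, df, lower.tail = FALSE))
    data.frame(channel = win$labels[i], ratio = ratio, p = p,
               pass = p >= alpha, note = "")
  })
  tab <- do.call(rbind, res)
  list(stationary = mean(tab$pass) >= channel_frac, table = tab)
}

#' Full preprocessing pipeline
#'
#' Fixed stage order: band-pass filter, decimate, common-average re-reference,
#' segment, stationarity-flag. Non-stationary windows are flagged but kept
#' unless `drop_nonstationary = TRUE`.
#'
#' @param rec an [recording()] object.
#' @param band length-2 numeric, band-pass edges in Hz.
#' @param target_fs decimation target in Hz (`NULL` keeps the input rate).
#' @param window_ms,overlap see [segment_windows()].
#' @param drop_nonstationary drop windows failing the variance-ratio test.
#' @param notch optional mains notch frequency in Hz.
#' @return list of stationarity-flagged `window_segment`s.
#' @export
preprocess <- function(rec, band = c(0.5, 45), target_fs = 128,
                       window_ms = 5000, overlap = 0.5,
                       drop_nonstationary = FALSE, notch = NULL) {
  rec <- bandpass_filter(rec, band[1L], band[2L], notch = notch)
  if (!is.null(target_fs) && target_fs != rec$fs)
    rec <- downsample(rec, target_fs)
  rec <- rereference_common_average(rec)
  wins <- segment_windows(rec, window_ms = window_ms, overlap = overlap)
  wins <- lapply(wins, function(w) {
    w$stationary <- variance_ratio_stationarity(w)$stationary
    w
  })
  if (drop_nonstationary)
    wins <- Filter(function(w) isTRUE(w$stationary), wins)
  wins
}

# coerce a bare matrix to a window_segment (tests / programmatic use)
as_window <- function(x, fs, labels = NULL, kinds = NULL) {
  if (inherits(x, "window_segment")) return(x)
  if (inherits(x, "mc_recording"))
    return(structure(list(samples = x$samples, fs = x$fs, start_s = 0,
                          stationary = NA, labels = x$labels, kinds = x$kinds,
                          emotion = x$emotion, subject_id = x$subject_id),
                     class = "window_segment"))
  x <- as.matrix(x)
  m <- nrow(x)
  structure(list(samples = x, fs = fs, start_s = 0, stationary = NA,
                 labels = labels %||% sprintf("ch%02d", seq_len(m)),
                 kinds = kinds %||% rep("EEG", m),
                 emotion = NULL, subject_id = NULL),
            class = "window_segment")
}
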