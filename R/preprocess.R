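# Cleaning, Laplacian derivation, band-pass filtering, epoching, Welch PSD.

new_epochs <- function(data, time_axis, labels, fs, channels, band = NULL) {
  dimnames(data) <- list(NULL, channels, NULL)
  structure(list(data = data, time = time_axis, labels = labels, fs = fs,
                 channels = channels, band = band,
                 kept = rep(TRUE, dim(data)[1])), class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_epochs> %d trials x %d channels x %d samples (t = [%.2f, %.2f] s @ %g Hz)\n",
              d[1], d[2], d[3], min(x$time), max(x$time), x$fs))
  if (!is.null(x$labels)) print(table(x$labels))
  if (!is.null(x$band)) cat(sprintf("  band: %.1f-%.1f Hz\n", x$band[1], x$band[2]))
  invisible(x)
}

subset_epochs <- function(epochs, trials = NULL, channels = NULL, time_idx = NULL) {
  e <- epochs
  d <- dim(e$data)
  if (is.logical(trials)) trials <- which(trials)
  if (!is.null(trials) && identical(length(trials), d[1]) &&
      all(trials == seq_len(d[1]))) trials <- NULL
  if (!is.null(channels) && identical(channels, e$channels)) channels <- NULL
  if (!is.null(trials)) {
    e$data <- e$data[trials, , , drop = FALSE]
    e$labels <- e$labels[trials]
    e$kept <- e$kept[trials]
  }
  if (!is.null(channels)) {
    ci <- match(channels, e$channels)
    if (anyNA(ci)) stopf("unknown channel(s): %s",
                         paste(channels[is.na(ci)], collapse = ", "))
    e$data <- e$data[, ci, , drop = FALSE]
    e$channels <- channels
  }
  if (!is.null(time_idx)) {
    e$data <- e$data[, , time_idx, drop = FALSE]
    e$time <- e$time[time_idx]
  }
  dimnames(e$data) <- list(NULL, e$channels, NULL)
  e
}

# restrict epochs to a time interval [t0, t1) in seconds relative to stimulus
segment_epochs <- function(epochs, t0, t1) {
  idx <- which(epochs$time >= t0 - 1e-9 & epochs$time < t1 - 1e-9)
  if (!length(idx)) stopf("segment [%g, %g) outside epoch time range", t0, t1)
  subset_epochs(epochs, time_idx = idx)
}

#' Surface-Laplacian derivation
#'
#' For each requested center channel, subtracts the mean of its M neighbor
#' channels: `s(t) = x0(t) - (1/M) * sum_c x_c(t)`. All involved channels are
#' weighted identically, independent of class; the filter suppresses
#' background activity common to the local channel group.
#'
#' @param x An `eeg_recording` or `eeg_epochs` object.
#' @param montage A `bci_montage` providing the neighbor map.
#' @param centers Channels to derive (default: all channels of `x` present in
#'   the montage with at least one neighbor available in `x`).
#' @return Same class as `x`, with one channel per center.
#' @export
laplacian <- function(x, montage, centers = NULL) UseMethod("laplacian")

lap_matrix <- function(montage, centers, available) {
  W <- matrix(0, length(centers), length(available),
              dimnames = list(centers, available))
  for (i in seq_along(centers)) {
    cc <- centers[i]
    nb <- intersect(montage$neighbors[[cc]], available)
    if (!length(nb)) stopf("channel %s has no neighbors available for Laplacian", cc)
    W[i, cc] <- 1
    W[i, nb] <- -1 / length(nb)
  }
  W
}

#' @export
laplacian.eeg_recording <- function(x, montage = x$montage, centers = NULL) {
  avail <- rownames(x$data)
  if (is.null(centers)) {
    centers <- avail[vapply(avail, function(cc)
      length(intersect(montage$neighbors[[cc]], avail)) > 0, TRUE)]
  }
  W <- lap_matrix(montage, centers, avail)
  out <- x
  out$data <- W %*% x$data
  out
}

#' @export
laplacian.eeg_epochs <- function(x, montage, centers = NULL) {
  avail <- x$channels
  if (is.null(centers)) {
    centers <- avail[vapply(avail, function(cc)
      length(intersect(montage$neighbors[[cc]], avail)) > 0, TRUE)]
  }
  W <- lap_matrix(montage, centers, avail)
  d <- dim(x$data)
  out <- x
  M <- W %*% matrix(aperm(x$data, c(2, 3, 1)), d[2], d[3] * d[1])
  out$data <- aperm(array(M, c(length(centers), d[3], d[1])), c(3, 1, 2))
  out$channels <- centers
  dimnames(out$data) <- list(NULL, centers, NULL)
  out
}

#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth applied forward-backward (zero phase), the standard
#' choice for ERD analysis where phase distortion would bias latency
#' estimates. Epochs are filtered trial by trial.
#'
#' @param x An `eeg_recording` or `eeg_epochs`.
#' @param band `(f_lo, f_hi)` in Hz, inside (0, fs/2).
#' @param order Butterworth order (default 4).
#' @return Same class as `x`, band annotation set.
#' @export
bandpass <- function(x, band, order = 4) UseMethod("bandpass")

check_band <- function(band, fs) {
  if (length(band) != 2 || band[1] <= 0 || band[2] <= band[1] || band[2] >= fs / 2) {
    stopf("band (%g, %g) must satisfy 0 < f_lo < f_hi < fs/2 = %g",
          band[1], band[2], fs / 2)
  }
}

#' @export
bandpass.eeg_recording <- function(x, band, order = 4) {
  check_band(band, x$fs)
  cf <- butter_coefs(order, band, x$fs)
  out <- x
  out$data <- t(filtfilt_mat(cf$b, cf$a, t(x$data)))
  rownames(out$data) <- rownames(x$data)
  out$band <- band
  out
}

#' @export
bandpass.eeg_epochs <- function(x, band, order = 4) {
  check_band(band, x$fs)
  cf <- butter_coefs(order, band, x$fs)
  d <- dim(x$data)
  # time x (trial, channel) matrix, filtered in one C-level pass
  M <- matrix(aperm(x$data, c(3, 1, 2)), d[3], d[1] * d[2])
  M <- filtfilt_mat(cf$b, cf$a, M)
  out <- x
  out$data <- aperm(array(M, c(d[3], d[1], d[2])), c(2, 3, 1))
  dimnames(out$data) <- list(NULL, x$channels, NULL)
  out$band <- band
  out
}

#' Segment a continuous recording into epochs
#'
#' One trial per stimulus marker, time 0 aligned to the marker sample.
#' Samples are taken half-open, `[start, stop)`, so an interval of
#' `(-2, 6)` s at 200 Hz yields exactly 1600 samples. Markers too close to a
#' recording edge are skipped with a warning.
#'
#' @param recording An `eeg_recording` with markers.
#' @param interval `(start, stop)` seconds relative to the stimulus.
#' @return An `eeg_epochs` object.
#' @export
epoch <- function(recording, interval = c(-2, 6)) {
  mk <- recording$markers
  if (is.null(mk) || nrow(mk) == 0) stopf("recording has no markers to epoch")
  fs <- recording$fs
  i0 <- round(interval[1] * fs)
  i1 <- round(interval[2] * fs)  # half-open: samples i0 .. i1-1 relative to marker
  nlen <- i1 - i0
  nsamp <- ncol(recording$data)
  starts <- mk$sample + i0
  ok <- starts >= 1 & (starts + nlen - 1) <= nsamp
  if (any(!ok)) {
    warnf("%d trial(s) too close to the recording edge were skipped", sum(!ok))
  }
  keep <- which(ok)
  idx <- rep(starts[keep], each = nlen) + rep(0:(nlen - 1), length(keep))
  M <- recording$data[, idx, drop = FALSE]      # channels x (time, trial)
  data <- aperm(array(M, c(nrow(recording$data), nlen, length(keep))), c(3, 1, 2))
  new_epochs(data, time_axis = (i0:(i1 - 1)) / fs, labels = mk$label[keep],
             fs = fs, channels = rownames(recording$data))
}

# Welch PSD of each column of X (time x series): linear power (muV^2/Hz) on
# the one-sided grid; Hann windows, segment means removed, mvfft-batched.
welch_matrix <- function(X, fs, window_s = 2, overlap = 0.5) {
  n <- nrow(X)
  nwin <- round(window_s * fs)
  if (n < nwin) stopf("signal shorter than one Welch window (%g s)", window_s)
  step <- max(1, round(nwin * (1 - overlap)))
  starts <- seq(1, n - nwin + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nwin - 1)) / (nwin - 1))  # Hann
  U <- sum(w^2)
  nf <- floor(nwin / 2) + 1
  acc <- matrix(0, nf, ncol(X))
  for (s in starts) {
    seg <- X[s:(s + nwin - 1), , drop = FALSE]
    seg <- sweep(seg, 2, colMeans(seg)) * w
    P <- abs(stats::mvfft(seg))^2 / (fs * U)
    half <- P[1:nf, , drop = FALSE]
    half[2:(nf - 1), ] <- 2 * half[2:(nf - 1), , drop = FALSE]
    acc <- acc + half
  }
  list(power = acc / length(starts), freqs = (0:(nf - 1)) * fs / nwin)
}

welch_vector <- function(x, fs, window_s = 2, overlap = 0.5) {
  out <- welch_matrix(matrix(x, ncol = 1), fs, window_s, overlap)
  list(power = drop(out$power), freqs = out$freqs)
}

#' Welch power spectral density
#'
#' Hann windows of `window_s` seconds with 50% overlap (defaults give 0.5 Hz
#' resolution at any sampling rate); values returned in dB
#' (`10*log10(muV^2/Hz)`).
#'
#' @param recording An `eeg_recording`.
#' @param channels Channel names (default: all).
#' @param freq_range `(f_lo, f_hi)` Hz to retain (default 2-35 Hz).
#' @param window_s Welch window length in seconds.
#' @param overlap Fractional window overlap.
#' @return An object of class `spectral_estimate`: list with `values`
#'   (channels x bins, dB), `freqs` (Hz), `resolution` (Hz).
#' @export
welch_psd <- function(recording, channels = NULL, freq_range = c(2, 35),
                      window_s = 2, overlap = 0.5) {
  if (is.null(channels)) channels <- rownames(recording$data)
  ci <- match(channels, rownames(recording$data))
  if (anyNA(ci)) stopf("unknown channel(s): %s",
                       paste(channels[is.na(ci)], collapse = ", "))
  wm <- welch_matrix(t(recording$data[ci, , drop = FALSE]), recording$fs,
                     window_s, overlap)
  sel <- which(wm$freqs >= freq_range[1] - 1e-9 & wm$freqs <= freq_range[2] + 1e-9)
  vals <- 10 * log10(t(wm$power[sel, , drop = FALSE]))
  dimnames(vals) <- list(channels, NULL)
  structure(list(values = vals, freqs = wm$freqs[sel],
                 resolution = recording$fs / round(window_s * recording$fs)),
            class = "spectral_estimate")
}

#' @export
print.spectral_estimate <- function(x, ...) {
  cat(sprintf("<spectral_estimate> %d channels, %.1f-%.1f Hz @ %.2f Hz\n",
              nrow(x$values), min(x$freqs), max(x$freqs), x$resolution))
  invisible(x)
}

#' Automatic channel and trial rejection
#'
#' Channels with impedance above `impedance_limit` are removed first. Then a
#' variance-based rule is iterated on the time window `window` (seconds after
#' the stimulus): each trial's standard deviation is computed (pooled over the
#' kept channels and window samples by default) and trials whose std exceeds
#' twice the mean std over all currently kept trials are rejected; the rule is
#' iterated until a pass rejects nothing.
#'
#' @param epochs An `eeg_epochs`.
#' @param montage A `bci_montage` carrying channel impedances; when `x` has
#'   channels without impedance metadata the impedance rule is skipped with a
#'   notice.
#' @param impedance_limit kOhm threshold (default 50).
#' @param window `(t0, t1)` seconds after stimulus used for the variance rule
#'   (default 0.5-4.5 s).
#' @param method `"pooled"` (default): one std per trial pooled over channels;
#'   `"per-channel-max"`: a trial's statistic is its worst channel std.
#' @return List with `epochs` (cleaned) and `report` (dropped channels,
#'   rejected trial indices per iteration, iteration count).
#' @export
clean <- function(epochs, montage, impedance_limit = 50, window = c(0.5, 4.5),
                  method = c("pooled", "per-channel-max")) {
  method <- match.arg(method)
  stopifnot(window[1] >= min(epochs$time), window[2] <= max(epochs$time) + 1 / epochs$fs)

  dropped <- character(0)
  have_imp <- epochs$channels %in% names(montage$impedance)
  if (!all(have_imp)) {
    message("impedance metadata missing for some channels; impedance rule skipped for them")
  }
  imp <- montage$impedance[epochs$channels[have_imp]]
  dropped <- names(imp)[imp > impedance_limit]
  keep_ch <- setdiff(epochs$channels, dropped)
  e <- subset_epochs(epochs, channels = keep_ch)

  tidx <- which(e$time >= window[1] - 1e-9 & e$time < window[2] - 1e-9)
  n_tr <- dim(e$data)[1]
  trial_stat <- vapply(seq_len(n_tr), function(tr) {
    seg <- e$data[tr, , tidx, drop = FALSE]
    if (method == "pooled") stats::sd(as.vector(seg))
    else max(apply(matrix(seg, dim(seg)[2], dim(seg)[3]), 1, stats::sd))
  }, 0)

  kept <- rep(TRUE, n_tr)
  rejected_iter <- list()
  it <- 0
  repeat {
    it <- it + 1
    m <- mean(trial_stat[kept])
    bad <- which(kept & trial_stat > 2 * m)
    if (!length(bad)) break
    rejected_iter[[it]] <- bad
    kept[bad] <- FALSE
    if (!any(kept)) {
      stopf("variance rule rejected all trials (threshold 2 x mean std)")
    }
  }
  out <- subset_epochs(e, trials = which(kept))
  list(epochs = out,
       report = list(dropped_channels = dropped,
                     rejected_trials = rejected_iter,
                     n_iterations = it,
                     kept_index = which(kept),
                     n_kept = sum(kept), n_rejected = sum(!kept)))
}
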