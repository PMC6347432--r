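# Signed-r2 discriminability, z-transform, and the subject-specific
# frequency-band / time-interval selection heuristics.

#' Signed squared point-biserial correlation
#'
#' `r2 = N1*N2/(N1+N2)^2 * (mu1-mu2)^2 / var(x)` with the population variance
#' over all observations, multiplied by the sign of `mu1 - mu2`. Its magnitude
#' equals the squared Pearson correlation between the feature and a binary
#' class coding; values near +-1 mark discriminative features.
#'
#' @param x Per-trial feature values.
#' @param labels Class label per trial (exactly two classes present).
#' @param classes Optional length-2 vector fixing class order (class 1 first);
#'   default: sorted unique labels.
#' @return Scalar in `[-1, 1]`.
#' @examples
#' signed_r2(c(1, 2, 3, 4), c(1, 1, 2, 2)) # -0.8
#' @export
signed_r2 <- function(x, labels, classes = NULL) {
  if (is.null(classes)) classes <- sort(unique(as.character(labels)))
  if (length(classes) != 2) stopf("signed_r2 needs exactly 2 classes, got %d",
                                  length(classes))
  labels <- as.character(labels)
  i1 <- labels == classes[1]; i2 <- labels == classes[2]
  n1 <- sum(i1); n2 <- sum(i2)
  if (n1 == 0 || n2 == 0) stopf("both classes must be present")
  v <- mean((x - mean(x))^2)  # population normalization
  if (v <= 0) stopf("zero pooled variance: statistic undefined")
  d <- mean(x[i1]) - mean(x[i2])
  sign(d) * (n1 * n2 / (n1 + n2)^2) * d^2 / v
}

# vectorized over columns of X (trials x features); returns signed r2 per column
signed_r2_cols <- function(X, labels, classes = NULL) {
  if (is.null(classes)) classes <- sort(unique(as.character(labels)))
  labels <- as.character(labels)
  i1 <- labels == classes[1]; i2 <- labels == classes[2]
  n1 <- sum(i1); n2 <- sum(i2)
  mu <- colMeans(X)
  v <- colMeans(sweep(X, 2, mu)^2)
  d <- colMeans(X[i1, , drop = FALSE]) - colMeans(X[i2, , drop = FALSE])
  out <- sign(d) * (n1 * n2 / (n1 + n2)^2) * d^2 / v
  out[v <= 0] <- 0
  out
}

#' Fisher z-transform of a (signed) correlation
#'
#' `z = arctanh(r)`, monotone and odd, used to make signed-r2 values
#' approximately normal before grand averaging across users. The printed
#' logarithmic form `ln((1+r)/(1-r))` equals `2*arctanh(r)`; set
#' `double = TRUE` for that variant.
#'
#' @param r Correlation value(s), `|r| < 1`; values at or beyond +-1 are
#'   capped with a warning.
#' @param double Use the doubled (log-ratio) variant.
#' @return z value(s).
#' @export
z_transform <- function(r, double = FALSE) {
  cap <- 1 - 1e-12
  if (any(abs(r) >= 1)) {
    warnf("|r| >= 1: capped before z-transform")
    r <- pmin(pmax(r, -cap), cap)
  }
  z <- atanh(r)
  if (double) 2 * z else z
}

#' Significance level for grand-average z maps
#'
#' The |z| contour corresponding to a significance level p under the
#' natural-log mapping used for grand-average maps: `|z| = -ln(p)`, e.g.
#' p = 0.05 -> 2.9957.
#'
#' @param p Significance level in (0, 1].
#' @return The |z| contour level.
#' @examples
#' significance_threshold(0.05)
#' @export
significance_threshold <- function(p) {
  if (!is.numeric(p) || any(p <= 0) || any(p > 1)) {
    stopf("p must be in (0, 1]")
  }
  -log(p)
}

# centered moving average, width k (odd); shrinking window at the edges
smooth_ma <- function(x, k) {
  if (k <= 1) return(x)
  h <- k %/% 2
  n <- length(x)
  cs <- c(0, cumsum(x))
  lo <- pmax(1, seq_len(n) - h)
  hi <- pmin(n, seq_len(n) + h)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# seed-and-grow: start at argmax of |score|, extend both bounds over
# contiguous bins with |score| >= max/3; then enforce a minimum width.
seed_and_grow <- function(score, axis, min_width) {
  a <- abs(score)
  if (all(!is.finite(a)) || max(a, na.rm = TRUE) <= 0) return(NULL)
  peak <- which.max(a)  # ties: earliest bin wins
  thr <- a[peak] / 3 * (1 - 1e-9)  # "not lower than 1/3", robust to rounding
  lo <- peak
  while (lo > 1 && a[lo - 1] >= thr) lo <- lo - 1
  hi <- peak
  while (hi < length(a) && a[hi + 1] >= thr) hi <- hi + 1
  # enforce minimum width, extending symmetrically within the axis
  while (axis[hi] - axis[lo] < min_width && (lo > 1 || hi < length(a))) {
    grow_lo <- lo > 1 && (hi == length(a) || a[lo - 1] >= a[hi + 1])
    if (grow_lo) lo <- lo - 1 else hi <- hi + 1
  }
  c(lo = lo, hi = hi, peak = peak)
}

# per-trial spectra of selected channels: list(power = trials x channels x bins
# in dB, freqs)
trial_spectra <- function(epochs, channels, freq_range = c(5, 35), window_s = 1) {
  d <- dim(epochs$data)
  ci <- match(channels, epochs$channels)
  nwin <- round(window_s * epochs$fs)
  if (d[3] < nwin) window_s <- d[3] / epochs$fs
  M <- matrix(aperm(epochs$data[, ci, , drop = FALSE], c(3, 1, 2)),
              d[3], d[1] * length(ci))
  wm <- welch_matrix(M, epochs$fs, window_s)
  sel <- which(wm$freqs >= freq_range[1] - 1e-9 & wm$freqs <= freq_range[2] + 1e-9)
  pow <- aperm(array(10 * log10(pmax(wm$power[sel, , drop = FALSE], 1e-20)),
                     c(length(sel), d[1], length(ci))), c(2, 3, 1))
  list(power = pow, freqs = wm$freqs[sel])
}

#' Subject-specific frequency band selection
#'
#' Computes, per Laplacian-derived motor channel and frequency bin, the signed
#' r2 of per-trial spectral power (dB), smooths it with a centered ~3 Hz
#' moving window, aggregates bins by the maximum |r2| across channels, then
#' seeds a band at the best bin and grows both bounds over contiguous bins
#' whose score stays at or above 1/3 of the initial maximum. A minimum band
#' width is enforced; if the map carries no discriminative information the
#' default band (8, 15) Hz is returned with a warning and a low-confidence
#' attribute.
#'
#' @param epochs Broad-band (or raw) `eeg_epochs` with two classes, ideally
#'   already restricted to the discriminative time interval.
#' @param montage A `bci_montage`.
#' @param freq_range Search range in Hz (default 5-35).
#' @param min_width Minimum band width in Hz (default 3).
#' @param smooth_hz Smoothing window in Hz (default 3).
#' @return `c(f_lo, f_hi)` in Hz, attribute `low_confidence` logical.
#' @export
select_frequency_band <- function(epochs, montage, freq_range = c(5, 35),
                                  min_width = 3, smooth_hz = 3) {
  stopifnot(length(unique(epochs$labels)) == 2)
  lap <- laplacian(epochs, montage, intersect(motor_channels(montage), epochs$channels))
  sp <- trial_spectra(lap, lap$channels, freq_range)
  freqs <- sp$freqs
  df <- if (length(freqs) > 1) freqs[2] - freqs[1] else 1
  k <- max(1, 2 * floor(smooth_hz / df / 2) + 1)  # odd bin count nearest smooth_hz
  rmat <- matrix(0, length(lap$channels), length(freqs))
  for (j in seq_along(lap$channels)) {
    r <- signed_r2_cols(sp$power[, j, , drop = TRUE], epochs$labels)
    rmat[j, ] <- smooth_ma(r, k)
  }
  winner <- apply(abs(rmat), 2, which.max)
  score <- rmat[cbind(winner, seq_along(freqs))]
  sg <- seed_and_grow(score, freqs, min_width)
  if (is.null(sg)) {
    warnf("no discriminative frequency content; falling back to (8, 15) Hz")
    return(structure(c(8, 15), low_confidence = TRUE))
  }
  structure(c(freqs[sg["lo"]], freqs[sg["hi"]]), low_confidence = FALSE)
}

# 200 ms moving-average band-power envelope of band-filtered epochs:
# trials x channels x time
power_envelope <- function(epochs, ma_s = 0.2) {
  k <- max(1, round(ma_s * epochs$fs))
  d <- dim(epochs$data)
  M <- matrix(aperm(epochs$data, c(3, 1, 2)), d[3], d[1] * d[2])^2
  # centered moving average via cumulative sums; edges (incomplete windows) 0
  CSr <- matrix(cumsum(M), d[3], ncol(M))
  CSr <- sweep(CSr, 2, c(0, CSr[d[3], -ncol(M)]))
  CS <- rbind(0, CSr)
  h1 <- (k - 1) %/% 2; h2 <- k - 1 - h1
  out <- matrix(0, d[3], ncol(M))
  valid <- (h1 + 1):(d[3] - h2)
  out[valid, ] <- (CS[valid + h2 + 1, , drop = FALSE] -
                   CS[valid - h1, , drop = FALSE]) / k
  aperm(array(out, c(d[3], d[1], d[2])), c(2, 3, 1))
}

#' Subject-specific time interval selection
#'
#' Same seed-and-grow rule as [select_frequency_band()], applied across time
#' to the signed r2 of the rectified, 200 ms moving-average band-power
#' envelope of Laplacian motor channels. A minimum interval length is
#' enforced; degenerate maps fall back to (750, 3500) ms with a warning.
#'
#' @param epochs Band-pass filtered `eeg_epochs` (two classes).
#' @param montage A `bci_montage`.
#' @param min_length_ms Minimum interval length (default 1000 ms).
#' @param search_from_ms Earliest interval start considered (default 0,
#'   the stimulus; the interval never extends before the epoch start).
#' @return `c(t_start, t_end)` in ms relative to the stimulus, attribute
#'   `low_confidence`.
#' @export
select_time_interval <- function(epochs, montage, min_length_ms = 1000,
                                 search_from_ms = 0) {
  stopifnot(length(unique(epochs$labels)) == 2)
  lap <- laplacian(epochs, montage, intersect(motor_channels(montage), epochs$channels))
  env <- power_envelope(lap)
  tsel <- which(lap$time * 1000 >= search_from_ms)
  tt <- lap$time[tsel] * 1000
  k <- max(1, 2 * floor(0.1 * epochs$fs) + 1)  # ~200 ms smoothing of the r2 course
  rmat <- matrix(0, dim(env)[2], length(tsel))
  for (j in seq_len(dim(env)[2])) {
    r <- signed_r2_cols(env[, j, tsel, drop = TRUE], epochs$labels)
    rmat[j, ] <- smooth_ma(r, k)
  }
  winner <- apply(abs(rmat), 2, which.max)
  score <- rmat[cbind(winner, seq_along(tt))]
  sg <- seed_and_grow(score, tt, min_length_ms)
  if (is.null(sg)) {
    warnf("no discriminative ERD time course; falling back to (750, 3500) ms")
    return(structure(c(750, 3500), low_confidence = TRUE))
  }
  structure(c(tt[sg["lo"]], tt[sg["hi"]]), low_confidence = FALSE)
}

#' Band/interval container
#'
#' @param f_lo,f_hi Frequency band bounds in Hz.
#' @param t_start,t_end Time interval in ms relative to the stimulus.
#' @param low_confidence Flag set when any selection fell back to defaults.
#' @return An object of class `band_interval`.
#' @export
band_interval <- function(f_lo, f_hi, t_start, t_end, low_confidence = FALSE) {
  stopifnot(f_lo < f_hi, t_start < t_end)
  structure(list(f_lo = f_lo, f_hi = f_hi, t_start = t_start, t_end = t_end,
                 low_confidence = low_confidence), class = "band_interval")
}

#' @export
print.band_interval <- function(x, ...) {
  cat(sprintf("<band_interval> %.1f-%.1f Hz, %d-%d ms%s\n", x$f_lo, x$f_hi,
              round(x$t_start), round(x$t_end),
              if (isTRUE(x$low_confidence)) " [low confidence]" else ""))
  invisible(x)
}

#' Joint selection of frequency band and time interval
#'
#' The standard ordering: band-pass filter in a large band (8-32 Hz), select
#' the time interval, segment, select the frequency band on the segmented
#' data, then re-select the time interval on data filtered in the selected
#' band.
#'
#' @param epochs Raw (unfiltered) `eeg_epochs`, two classes.
#' @param montage A `bci_montage`.
#' @param broad_band Initial wide filter band (default `c(8, 32)` Hz).
#' @return A [band_interval()], `low_confidence` set if any stage fell back.
#' @export
select_parameters <- function(epochs, montage, broad_band = c(8, 32)) {
  wide <- bandpass(epochs, broad_band)
  ti1 <- select_time_interval(wide, montage)
  seg <- segment_epochs(epochs, ti1[1] / 1000, ti1[2] / 1000)
  band <- select_frequency_band(seg, montage)
  narrow <- bandpass(epochs, band)
  ti2 <- select_time_interval(narrow, montage)
  low <- isTRUE(attr(ti1, "low_confidence")) || isTRUE(attr(band, "low_confidence")) ||
    isTRUE(attr(ti2, "low_confidence"))
  band_interval(band[1], band[2], ti2[1], ti2[2], low_confidence = low)
}

#' Select the representative SMR channel
#'
#' The Laplacian-derived candidate channel whose log band power (within the
#' subject-specific band and interval) has the highest squared point-biserial
#' correlation with the class labels. Candidates are the motor-area channels;
#' `include_parietal` adds the parieto-occipital group (used for
#' motor-observation runs). Ties break by candidate-list order.
#'
#' @param epochs Raw `eeg_epochs`, two classes.
#' @param bi A [band_interval()].
#' @param montage A `bci_montage`.
#' @param include_parietal Extend the candidate set.
#' @return Channel label; attribute `r2` carries the per-candidate map.
#' @export
select_smr_channel <- function(epochs, bi, montage, include_parietal = FALSE) {
  filt <- bandpass(epochs, c(bi$f_lo, bi$f_hi))
  smr_channel_core(filt, bi, montage, include_parietal)
}

# as select_smr_channel, but on epochs already filtered in the band
smr_channel_core <- function(filt, bi, montage, include_parietal = FALSE) {
  epochs <- filt
  cand <- intersect(motor_channels(montage), epochs$channels)
  if (include_parietal) {
    cand <- c(cand, intersect(parietal_channels(montage), epochs$channels))
  }
  if (!length(cand)) stopf("empty SMR-channel candidate set")
  seg <- segment_epochs(filt, bi$t_start / 1000, bi$t_end / 1000)
  lap <- laplacian(seg, montage, cand)
  d <- dim(lap$data)
  logbp <- matrix(0, d[1], d[2])
  for (j in seq_len(d[2])) {
    logbp[, j] <- log(apply(lap$data[, j, , drop = TRUE], 1, stats::var))
  }
  r2 <- signed_r2_cols(logbp, epochs$labels)
  names(r2) <- cand
  structure(cand[which.max(abs(r2))], r2 = r2)
}
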