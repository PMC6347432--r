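# Vectorized zero-phase Butterworth filtering. Coefficients come from
# signal::butter; the forward-backward pass is applied in the frequency domain
# as the squared magnitude response |H|^2 (the steady-state response of
# filtfilt), batched over all columns with one FFT pair. Columns are extended
# to a 2-3-5-smooth FFT length by a crossfade of odd reflections, which keeps
# the circular signal continuous and the edge transients inside the pad.

butter_coefs <- function(order, band, fs) {
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  list(b = bf$b, a = bf$a)
}

# |H(e^{j w})|^2 of the rational filter b/a on an n-point DFT grid
iir_mag2 <- function(b, a, n) {
  w <- 2 * pi * (0:(n - 1)) / n
  ee <- exp(-1i * w)
  E <- outer(ee, 0:(max(length(b), length(a)) - 1), "^")
  H <- (E[, seq_along(b), drop = FALSE] %*% b) /
    (E[, seq_along(a), drop = FALSE] %*% a)
  as.vector(abs(H)^2)
}

# zero-phase (forward-backward) filtering of each column of X (time x series)
filtfilt_mat <- function(b, a, X) {
  n <- nrow(X)
  np <- stats::nextn(n + max(256, ceiling(n / 8)), c(2, 3, 5))
  L <- np - n
  # odd reflection off the end, crossfaded into an odd reflection approaching
  # the start, so the periodic extension is continuous at both seams
  ie <- pmax(n - seq_len(L), 1)
  is <- pmin(1 + (L - seq_len(L) + 1), n)
  wgt <- seq_len(L) / (L + 1)
  endv <- matrix(X[n, ], L, ncol(X), byrow = TRUE)
  stav <- matrix(X[1, ], L, ncol(X), byrow = TRUE)
  ext <- (1 - wgt) * (2 * endv - X[ie, , drop = FALSE]) +
    wgt * (2 * stav - X[is, , drop = FALSE])
  Xp <- rbind(X, ext)
  G <- iir_mag2(b, a, np)
  Y <- stats::mvfft(Xp) * G
  out <- Re(stats::mvfft(Y, inverse = TRUE)) / np
  out[seq_len(n), , drop = FALSE]
}
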