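# Cleaning, Laplacian, filtering, epoching, Welch spectra.

test_that("impedance rule drops channels above the limit", {
  mnt <- make_montage("motor27", impedances = c(C3 = 60))
  e <- make_var_epochs(n_per_class = 5, vars = list(rep(1, 27), rep(1, 27)),
                       nt = 500, fs = 100)
  e$channels <- mnt$channels
  dimnames(e$data) <- list(NULL, mnt$channels, NULL)
  res <- clean(e, mnt, impedance_limit = 50, window = c(0.5, 4.5))
  expect_identical(res$report$dropped_channels, "C3")
  expect_false("C3" %in% res$epochs$channels)
})

test_that("variance rule rejects exactly the aberrant trial and reaches a fixed point", {
  mnt <- make_montage()
  n <- 20; nch <- 27; nt <- 500; fs <- 100
  data <- array(0, c(n, nch, nt))
  set.seed(42)
  base <- array(rnorm(n * nch * nt), c(n, nch, nt))
  # normalize every trial to pooled std exactly 1, then blow up trial 20
  for (i in seq_len(n)) data[i, , ] <- base[i, , ] / sd(as.vector(base[i, , ]))
  data[20, , ] <- data[20, , ] * 10
  e <- smrbci:::new_epochs(data, seq(0, by = 1 / fs, length.out = nt),
                           rep(c("A", "B"), 10), fs, mnt$channels)
  # hand iteration on the 20 stds (19 x 1, 1 x 10): mean 1.45, cut 2.9 -> trial
  # 20 out; second pass mean 1, cut 2 -> nothing: two iterations, one rejection
  res <- clean(e, mnt, window = c(0.5, 4.5))
  expect_identical(res$report$rejected_trials[[1]], 20L)
  expect_equal(res$report$n_iterations, 2)
  expect_equal(res$report$n_kept, 19)
  expect_identical(res$report$kept_index, 1:19)

  # identical-variance trials: zero rejections in a single pass
  e0 <- smrbci:::new_epochs(data[1:19, , , drop = FALSE],
                            seq(0, by = 1 / fs, length.out = nt),
                            rep("A", 19), fs, mnt$channels)
  res0 <- clean(e0, mnt, window = c(0.5, 4.5))
  expect_equal(res0$report$n_rejected, 0)
  expect_equal(res0$report$n_iterations, 1)
})

test_that("Laplacian derivation implements the 1/M neighbor weighting", {
  mnt <- make_montage()
  fs <- 100
  tt <- seq(0, 2, by = 1 / fs)[-1]
  n <- length(tt)
  # identical signal everywhere cancels exactly
  rec <- smrbci:::new_recording(matrix(rep(sin(2 * pi * 5 * tt), each = 27),
                                       27, n, byrow = FALSE), fs, NULL, mnt)
  rec$data <- matrix(sin(2 * pi * 5 * tt), 27, n, byrow = TRUE)
  rownames(rec$data) <- mnt$channels
  out <- laplacian(rec, mnt, c("C3", "Cz"))
  expect_lt(max(abs(out$data)), 1e-12)

  # center 2*sin with all four neighbors sin -> sin
  rec2 <- rec
  rec2$data["C3", ] <- 2 * sin(2 * pi * 5 * tt)
  rec2$data[mnt$neighbors$C3, ] <- matrix(sin(2 * pi * 5 * tt), 4, n, byrow = TRUE)
  out2 <- laplacian(rec2, mnt, "C3")
  expect_equal(as.vector(out2$data), sin(2 * pi * 5 * tt), tolerance = 1e-12)

  # M = 1 reduces to the pairwise difference (POz has one neighbor, Pz)
  expect_length(mnt$neighbors$POz, 1)
  rec3 <- rec
  rec3$data["POz", ] <- rnorm(n)
  rec3$data["Pz", ] <- rnorm(n)
  out3 <- laplacian(rec3, mnt, "POz")
  expect_equal(as.vector(out3$data),
               rec3$data["POz", ] - rec3$data[mnt$neighbors$POz, ],
               tolerance = 1e-12)
})

test_that("Laplacian is linear", {
  mnt <- make_montage()
  set.seed(5)
  mk <- function() {
    r <- smrbci:::new_recording(matrix(rnorm(27 * 300), 27, 300), 100, NULL, mnt)
    rownames(r$data) <- mnt$channels
    r
  }
  x <- mk(); y <- mk()
  z <- x; z$data <- 2 * x$data + 3 * y$data
  lz <- laplacian(z, mnt, c("C3", "C4"))$data
  lx <- laplacian(x, mnt, c("C3", "C4"))$data
  ly <- laplacian(y, mnt, c("C3", "C4"))$data
  expect_equal(lz, 2 * lx + 3 * ly, tolerance = 1e-12)
})

test_that("band-pass keeps the pass band and rejects out-of-band content", {
  fs <- 200
  tt <- seq(1 / fs, 20, by = 1 / fs)
  mk <- function(f0) {
    r <- structure(list(data = matrix(sin(2 * pi * f0 * tt), 1), fs = fs,
                        markers = NULL, montage = NULL, run_type = "rest"),
                   class = "eeg_recording")
    rownames(r$data) <- "x"
    r
  }
  mid <- 1000:3000
  in_band <- bandpass(mk(10), c(8, 12))
  expect_equal(max(abs(in_band$data[1, mid])), 1, tolerance = 0.05)
  out_band <- bandpass(mk(40), c(8, 12))
  expect_lt(20 * log10(max(abs(out_band$data[1, mid]))), -20)
  # idempotence on pass-band content away from the edges
  once <- bandpass(mk(10), c(8, 12))
  twice <- bandpass(once, c(8, 12))
  expect_equal(twice$data[1, mid], once$data[1, mid], tolerance = 0.02)
  expect_error(bandpass(mk(10), c(8, 150)), "fs/2")
  expect_identical(in_band$band, c(8, 12))
})

test_that("epoching is half-open, marker-aligned and edge-safe", {
  mnt <- make_montage()
  p <- make_user_profile("III", seed = 6)
  r <- simulate_run(p, run_spec("MI-Cb", 25), mnt, seed = 61)
  ep <- epoch(r, c(-2, 6))
  expect_equal(dim(ep$data), c(75, 27, 1600))  # 75 trials of 8 s at 200 Hz
  expect_equal(ep$time[1], -2)
  expect_equal(diff(ep$time)[1], 1 / r$fs)
  expect_identical(ep$labels, r$markers$label)
  ep2 <- epoch(r, c(0, 0.5))
  expect_equal(dim(ep2$data)[3], 100)  # 0.5 * fs samples, half-open
  # marker too close to the start is skipped with a warning
  r$markers$sample[1] <- 10L
  expect_warning(ep3 <- epoch(r, c(-2, 6)), "skipped")
  expect_equal(dim(ep3$data)[1], 74)
})

test_that("Welch spectra are calibrated", {
  fs <- 200
  set.seed(8)
  # white noise with variance s^2: flat PSD at s^2/(fs/2)
  s2 <- 4
  r <- structure(list(data = matrix(rnorm(fs * 120, sd = sqrt(s2)), 1), fs = fs,
                      markers = NULL, montage = NULL, run_type = "rest"),
                 class = "eeg_recording")
  rownames(r$data) <- "x"
  psd <- welch_psd(r, "x", freq_range = c(5, 35))
  expect_equal(psd$resolution, 0.5)
  theory <- 10 * log10(s2 / (fs / 2))
  expect_lt(abs(mean(psd$values) - theory), 0.5)
  expect_lt(sd(psd$values), 1.5)
  # pure 10 Hz tone peaks in the 10 Hz bin
  tone <- r
  tone$data[1, ] <- sin(2 * pi * 10 * seq_len(fs * 120) / fs)
  pt <- welch_psd(tone, "x", freq_range = c(5, 35))
  expect_equal(pt$freqs[which.max(pt$values)], 10)
  short <- r; short$data <- short$data[, 1:100, drop = FALSE]
  expect_error(welch_psd(short, "x"), "shorter")
})
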