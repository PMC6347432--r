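# Synthetic EEG generation.
#
# The generator is built so that the analytic PSD of the Laplacian derivation
# at a source's center channel equals the profile's spectral model, which makes
# parameter-recovery tests exact in expectation:
#   * background activity: independent per-channel Gaussian noise, spectrally
#     shaped by inverse FFT of sqrt(PSD) with random phases, scaled so that the
#     4-neighbor Laplacian reproduces the model noise curve n(f);
#   * mu/beta idle rhythm: one narrowband shaped-noise oscillator per source
#     (C3, C4, Cz, POz), mixed into channels with a Gaussian spatial kernel
#     (sd = one inter-electrode spacing) and pre-scaled by the inverse
#     Laplacian gain of its center;
#   * ERD: multiplicative attenuation of the oscillator envelope of the
#     class-contralateral source, amplitude gain sqrt(1 - depth), with 150 ms
#     cosine ramps.

# profile spectral model, dB domain, on frequency grid f (Hz)
model_psd_db <- function(profile, f, noise_only = FALSE, peak_scale = c(1, 1)) {
  np <- profile$noise_params; pp <- profile$peak_params
  fe <- pmax(f, 1)  # low-frequency cap: recordings are high-pass limited
  v <- np[["k_n1"]] + np[["k_n2"]] * fe^(-np[["lambda"]])
  if (!noise_only) {
    v <- v + peak_scale[1] * pp[["k_alpha"]] *
      exp(-(f - pp[["mu_alpha"]])^2 / (2 * pp[["sigma_alpha"]]^2)) +
      peak_scale[2] * pp[["k_beta"]] *
      exp(-(f - pp[["mu_beta"]])^2 / (2 * pp[["sigma_beta"]]^2))
  }
  unname(v)
}

db_to_lin <- function(db) 10^(db / 10)

# Gaussian processes with prescribed one-sided PSD (linear, muV^2/Hz), one per
# column; psd_fun(f) evaluated on the FFT grid; DC and Nyquist set to zero.
shaped_noise_mat <- function(n, fs, psd_fun, k = 1) {
  m <- stats::nextn(n, c(2, 3, 5))  # smooth FFT length; truncation keeps the PSD
  kmax <- floor((m - 1) / 2)
  f <- (1:kmax) * fs / m
  amp <- sqrt(pmax(psd_fun(f), 0) * fs * m / 2)
  Z <- matrix(complex(real = stats::rnorm(kmax * k),
                      imaginary = stats::rnorm(kmax * k)), kmax, k) / sqrt(2)
  X <- matrix(complex(real = 0), m, k)
  X[2:(kmax + 1), ] <- amp * Z
  X[m:(m - kmax + 1), ] <- Conj(X[2:(kmax + 1), , drop = FALSE])
  out <- Re(stats::mvfft(X, inverse = TRUE)) / m
  out[seq_len(n), , drop = FALSE]
}

shaped_noise <- function(n, fs, psd_fun) shaped_noise_mat(n, fs, psd_fun, 1)[, 1]

# spatial mixing weights of a source at channel `center` into all channels
source_mixing <- function(montage, center, sigma = 1) {
  d2 <- rowSums((montage$pos - matrix(montage$pos[center, ], nrow(montage$pos), 2,
                                      byrow = TRUE))^2)
  exp(-d2 / (2 * sigma^2))
}

# Laplacian gain of a source field at its own center
lap_gain <- function(montage, center) {
  w <- source_mixing(montage, center)
  nb <- montage$neighbors[[center]]
  unname(w[center] - mean(w[nb]))
}

erd_source_for <- function(class_label) {
  switch(class_label, Left = "C4", Right = "C3", Foot = "Cz",
         stopf("unknown class label '%s'", class_label))
}

# balanced, block-randomized marker table
make_markers <- function(spec) {
  classes <- spec$classes
  total <- spec$n_trials_per_class * length(classes)
  per_block <- spec$block_size
  n_blocks <- ceiling(total / per_block)
  labs <- character(0)
  for (b in seq_len(n_blocks)) {
    block <- sample(rep(classes, per_block / length(classes)))
    labs <- c(labs, block)
  }
  labs <- labs[seq_len(total)]
  span <- trial_span_s(spec)
  onset <- (seq_len(total) - 1) * span + spec$baseline_s
  data.frame(sample = as.integer(round(onset * spec$sampling_rate)) + 1L,
             label = labs, stringsAsFactors = FALSE)
}

new_recording <- function(data, fs, markers, montage, run_type = "rest") {
  rownames(data) <- montage$channels
  structure(list(data = data, fs = fs, markers = markers, montage = montage,
                 run_type = run_type), class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s: %d channels x %d samples (%.1f s @ %g Hz), %d markers\n",
              x$run_type, nrow(x$data), ncol(x$data), ncol(x$data) / x$fs, x$fs,
              if (is.null(x$markers)) 0L else nrow(x$markers)))
  invisible(x)
}

# shared generator core: background + sources with per-source amplitude envelope
generate_recording <- function(profile, montage, n, fs, markers = NULL,
                               run_type = "rest", depth_scale = 1) {
  nchan <- length(montage$channels)
  m_ref <- 4  # Laplacian neighbor count of the central motor channels
  noise_lin <- function(f) db_to_lin(model_psd_db(profile, f, noise_only = TRUE))
  bg_psd <- function(f) noise_lin(f) / (1 + 1 / m_ref)
  data <- t(shaped_noise_mat(n, fs, bg_psd, nchan))

  sources <- c("C3", "C4", "Cz", "POz")
  peak_scales <- list(C3 = c(1, 1), C4 = c(1, 1), Cz = c(1, 1), POz = c(0.7, 0))
  type_scale <- switch(run_type, MO = 0.35, 1)
  for (s in sources) {
    ps <- peak_scales[[s]]
    if (all(ps * unname(profile$peak_params[c("k_alpha", "k_beta")]) == 0)) next
    g <- lap_gain(montage, s)
    delta <- function(f) {
      pmax(db_to_lin(model_psd_db(profile, f, peak_scale = ps)) - noise_lin(f), 0) / g^2
    }
    src <- shaped_noise(n, fs, delta)
    if (!is.null(markers) && nrow(markers) > 0) {
      env <- rep(1, n)
      for (i in seq_len(nrow(markers))) {
        cls <- markers$label[i]
        target <- if (isTRUE(profile$parietal_modulation)) "POz" else erd_source_for(cls)
        if (target != s) next
        depth <- min(max(profile$erd_depth[[cls]] * depth_scale * type_scale, 0), 0.97)
        if (depth <= 0) next
        on <- markers$sample[i] + round(profile$erd_latency * fs)
        off <- min(on + round(profile$erd_duration * fs), n)
        if (on >= n) next
        gain <- sqrt(1 - depth)
        ramp <- round(0.15 * fs)
        idx <- on:off
        prof_gain <- rep(gain, length(idx))
        r1 <- seq_len(min(ramp, length(idx)))
        prof_gain[r1] <- 1 + (gain - 1) * (1 - cos(pi * r1 / ramp)) / 2
        r2 <- seq_len(min(ramp, length(idx)))
        prof_gain[length(idx) + 1 - r2] <-
          pmax(prof_gain[length(idx) + 1 - r2],
               1 + (gain - 1) * (1 - cos(pi * r2 / ramp)) / 2)
        env[idx] <- env[idx] * prof_gain
      }
      src <- src * env
    }
    mix <- source_mixing(montage, s)
    sig <- which(mix > 1e-4)  # channels with non-negligible source pickup
    data[sig, ] <- data[sig, , drop = FALSE] + tcrossprod(mix[sig], src)
  }
  data
}

#' Simulate a rest recording
#'
#' Eyes-open rest: background 1/f-type activity plus the profile's idle mu and
#' beta rhythms over the motor sources, no task modulation. The Welch PSD of
#' the Laplacian derivation at C3/C4 converges to the profile's spectral model
#' as duration grows.
#'
#' @param profile A [make_user_profile()] object.
#' @param duration Duration in seconds (>= 30 s recommended; 120 s gives a
#'   stable predictor estimate).
#' @param montage A [make_montage()] object.
#' @param seed Integer seed (default: derived from the profile seed).
#' @param fs Sampling rate in Hz.
#' @return An `eeg_recording` without markers.
#' @export
simulate_rest <- function(profile, duration = 120, montage = make_montage(),
                          seed = derive_seed(profile$seed, "rest"), fs = 200) {
  n <- round(duration * fs)
  data <- with_local_seed(seed, generate_recording(profile, montage, n, fs))
  new_recording(data, fs, NULL, montage, "rest")
}

#' Simulate one task run
#'
#' Generates a continuous recording with block-randomized, class-balanced
#' stimulus markers. During each trial the oscillator envelope of the
#' class-contralateral source (Left -> C4, Right -> C3, Foot -> Cz) is
#' attenuated by the profile's ERD depth from `erd_latency` after the stimulus
#' for `erd_duration` seconds. Motor-observation runs use a reduced modulation
#' (35% of the profile depth).
#'
#' @param profile A [make_user_profile()] object.
#' @param spec A [run_spec()].
#' @param montage A [make_montage()] object.
#' @param seed Integer seed.
#' @param depth_scale Extra multiplier on ERD depth (used for feedback-run
#'   drift by [simulate_session()]).
#' @return An `eeg_recording` with a `markers` data frame (sample, label).
#' @export
simulate_run <- function(profile, spec, montage = make_montage(),
                         seed = derive_seed(profile$seed, spec$run_type),
                         depth_scale = 1) {
  if (!all(spec$classes %in% profile$class_set)) {
    stopf("run classes not in profile class_set")
  }
  if (spec$run_type == "rest") {
    return(simulate_rest(profile, spec$duration_s, montage, seed,
                         fs = spec$sampling_rate))
  }
  fs <- spec$sampling_rate
  total <- spec$n_trials_per_class * length(spec$classes)
  n <- round(total * trial_span_s(spec) * fs)
  out <- with_local_seed(seed, {
    markers <- make_markers(spec)
    data <- generate_recording(profile, montage, n, fs, markers,
                               run_type = spec$run_type, depth_scale = depth_scale)
    list(markers = markers, data = data)
  })
  new_recording(out$data, fs, out$markers, montage, spec$run_type)
}

#' Simulate a full session
#'
#' Runs the plan in order. For motor-imagery feedback runs the ERD depth is
#' multiplied by `profile$drift^j` for the j-th feedback run, modelling the
#' run-by-run pattern deterioration seen in users whose feedback performance
#' falls short of their calibration performance.
#'
#' @param profile A [make_user_profile()] object.
#' @param session_plan List of [run_spec()]s, e.g. [default_session_plan()].
#' @param montage A [make_montage()] object.
#' @param seed Master seed for the session (default: profile seed).
#' @return An object of class `user_session`: list with `recordings` (named
#'   list of `eeg_recording`), `profile` and `plan`.
#' @export
simulate_session <- function(profile, session_plan = default_session_plan(),
                             montage = make_montage(),
                             seed = profile$seed) {
  if (!length(session_plan)) stopf("session plan is empty")
  if (is.null(names(session_plan)) || any(!nzchar(names(session_plan)))) {
    names(session_plan) <- paste0(vapply(session_plan, `[[`, "", "run_type"),
                                  "_", seq_along(session_plan))
  }
  fb_i <- 0
  recs <- list()
  for (nm in names(session_plan)) {
    sp <- session_plan[[nm]]
    scale <- 1
    if (sp$run_type == "MI-Fb") {
      fb_i <- fb_i + 1
      scale <- profile$drift^fb_i
    }
    rec <- simulate_run(profile, sp, montage, seed = derive_seed(seed, nm),
                        depth_scale = scale)
    rec$markers <- if (!is.null(rec$markers)) cbind(rec$markers, run_id = nm)
    recs[[nm]] <- rec
  }
  structure(list(recordings = recs, profile = profile, plan = session_plan,
                 montage = montage, seed = seed), class = "user_session")
}

#' @export
print.user_session <- function(x, ...) {
  cat(sprintf("<user_session> template %s, %d runs: %s\n",
              x$profile$category_template, length(x$recordings),
              paste(names(x$recordings), collapse = ", ")))
  invisible(x)
}
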