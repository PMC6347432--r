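#' User profile templates for synthetic sessions
#'
#' Creates the generative ground truth for one simulated user. Templates map
#' to the three screening categories: `"I"` (strong SMR idle rhythm, deep
#' class-specific ERD, stable across feedback), `"II"` (moderate idle rhythm
#' and ERD during calibration, ERD depth decaying run-by-run during feedback,
#' modelling pattern deterioration) and `"III"` (weak/absent idle rhythm, near
#' zero class-specific modulation).
#'
#' The rest spectrum of a profile, in dB, is
#' `n(f) + g_a(f) + g_b(f)` with `n(f) = k_n1 + k_n2 * f^-lambda` and
#' unnormalized Gaussian peaks of heights `k_alpha`, `k_beta` (dB) at
#' `mu_alpha` (mu band) and `mu_beta` (beta band). ERD is a multiplicative
#' attenuation of the oscillator envelope over the class-contralateral source,
#' so the fractional band-power drop equals `erd_depth` by construction.
#'
#' Small per-seed jitter is applied to peak frequencies, amplitudes and ERD
#' depths so that a cohort of one template is not a cohort of clones;
#' given the same seed the profile is fully deterministic.
#'
#' @param category_template `"I"`, `"II"` or `"III"`.
#' @param seed Integer seed controlling the jitter.
#' @return An object of class `user_profile`.
#' @examples
#' p <- make_user_profile("I", seed = 1)
#' p$peak_params[["k_alpha"]]
#' @export
make_user_profile <- function(category_template = c("I", "II", "III"), seed = 1L) {
  category_template <- match.arg(category_template)
  base <- switch(category_template,
    I = list(erd = c(Left = 0.80, Right = 0.74, Foot = 0.55), drift = 1.0,
             k_alpha = 6.0, k_beta = 2.0, erd_duration = 3.4),
    II = list(erd = c(Left = 0.62, Right = 0.56, Foot = 0.46), drift = 0.42,
              k_alpha = 4.0, k_beta = 1.5, erd_duration = 3.0),
    III = list(erd = c(Left = 0.06, Right = 0.05, Foot = 0.04), drift = 1.0,
               k_alpha = 0.6, k_beta = 0.25, erd_duration = 2.5))
  prof <- with_local_seed(derive_seed(seed, paste0("profile", category_template)), {
    erd <- pmin(pmax(base$erd * exp(stats::rnorm(3, 0, 0.06)), 0), 0.97)
    if (category_template == "III") erd <- pmin(erd, 0.12)
    mu_a <- min(max(stats::rnorm(1, 10.5, 0.8), 8), 13)
    list(
      category_template = category_template,
      class_set = c("Left", "Right", "Foot"),
      erd_depth = erd,
      mu_freq = mu_a,
      beta_freq = min(max(2 * mu_a + stats::rnorm(1, 0, 0.5), 16), 28),
      noise_params = c(lambda = stats::runif(1, 1.0, 1.5),
                       k_n1 = stats::rnorm(1, -2, 0.5),
                       k_n2 = stats::runif(1, 14, 22)),
      peak_params = c(k_alpha = max(base$k_alpha * exp(stats::rnorm(1, 0, 0.12)), 0),
                      mu_alpha = mu_a, sigma_alpha = stats::runif(1, 1.1, 1.8),
                      k_beta = max(base$k_beta * exp(stats::rnorm(1, 0, 0.15)), 0),
                      mu_beta = NA, sigma_beta = stats::runif(1, 1.8, 2.8)),
      drift = base$drift,
      erd_latency = 0.4,
      erd_duration = base$erd_duration,
      parietal_modulation = FALSE,
      seed = as.integer(seed)
    )
  })
  prof$peak_params[["mu_beta"]] <- prof$beta_freq
  stopifnot(all(prof$erd_depth >= 0 & prof$erd_depth <= 1), prof$drift > 0,
            prof$peak_params[["mu_alpha"]] >= 7, prof$peak_params[["mu_alpha"]] <= 14,
            prof$peak_params[["mu_beta"]] >= 15, prof$peak_params[["mu_beta"]] <= 30)
  structure(prof, class = "user_profile")
}

#' @export
print.user_profile <- function(x, ...) {
  cat(sprintf("<user_profile> template %s (seed %d)\n", x$category_template, x$seed))
  cat(sprintf("  ERD depth: L %.2f R %.2f F %.2f  drift %.2f  latency %.1fs dur %.1fs\n",
              x$erd_depth[["Left"]], x$erd_depth[["Right"]], x$erd_depth[["Foot"]],
              x$drift, x$erd_latency, x$erd_duration))
  cat(sprintf("  peaks: k_a %.2f dB @ %.1f Hz (sd %.1f), k_b %.2f dB @ %.1f Hz (sd %.1f)\n",
              x$peak_params[["k_alpha"]], x$peak_params[["mu_alpha"]],
              x$peak_params[["sigma_alpha"]], x$peak_params[["k_beta"]],
              x$peak_params[["mu_beta"]], x$peak_params[["sigma_beta"]]))
  invisible(x)
}

#' Run specification
#'
#' Trial timing follows the screening protocol: calibration-style trials have
#' a 2 s pre-stimulus baseline, 4 s cue (stimulus at t = 0) and a 2 s blank,
#' 8 s in total; feedback trials keep the 4 s activity period but a 3 s
#' result/blank phase, 9 s in total. Classes are equally distributed within
#' each block of `block_size` trials.
#'
#' @param run_type One of `"rest"`, `"MO"`, `"ME"`, `"MI-Cb"`, `"MI-Fb"`.
#' @param n_trials_per_class Trials per class (ignored for rest).
#' @param classes Class labels used in the run.
#' @param baseline_s,cue_s,post_s Trial phase durations in seconds.
#' @param sampling_rate Sampling rate in Hz (default 200).
#' @param block_size Trials per block (class-balanced within block).
#' @param duration_s Rest recording duration (rest runs only).
#' @return An object of class `run_spec`.
#' @export
run_spec <- function(run_type = c("MI-Cb", "MI-Fb", "ME", "MO", "rest"),
                     n_trials_per_class = 25,
                     classes = c("Left", "Right", "Foot"),
                     baseline_s = 2, cue_s = 4,
                     post_s = if (run_type[1] == "MI-Fb") 3 else 2,
                     sampling_rate = 200,
                     block_size = if (run_type[1] == "MI-Fb") 20 else 15,
                     duration_s = 120) {
  run_type <- match.arg(run_type)
  if (run_type == "MI-Fb" && length(classes) != 2) {
    stopf("feedback runs use exactly 2 classes, got %d", length(classes))
  }
  if (run_type != "rest" && n_trials_per_class < 1) stopf("n_trials_per_class must be >= 1")
  n_classes <- length(classes)
  if (run_type != "rest" && block_size %% n_classes != 0) {
    stopf("block_size (%d) must be a multiple of the number of classes (%d)",
          block_size, n_classes)
  }
  structure(list(run_type = run_type, n_trials_per_class = n_trials_per_class,
                 classes = classes, baseline_s = baseline_s, cue_s = cue_s,
                 post_s = post_s, sampling_rate = sampling_rate,
                 block_size = block_size, duration_s = duration_s),
            class = "run_spec")
}

trial_span_s <- function(spec) spec$baseline_s + spec$cue_s + spec$post_s

#' Default session plan
#'
#' Three motor-imagery calibration runs (75 trials each, 25 per class, three
#' classes; 225 labelled calibration trials in total) followed by three
#' two-class feedback runs of 100 trials (50 per class), plus an initial rest
#' recording used for the rest-spectrum predictor.
#'
#' @param feedback_classes The two classes used in the feedback runs.
#' @param sampling_rate Hz.
#' @param rest_duration_s Rest recording length in seconds.
#' @param include_rest Include the rest recording (default TRUE).
#' @return List of `run_spec` objects, named rest, MI-Cb1..3, MI-Fb1..3.
#' @export
default_session_plan <- function(feedback_classes = c("Left", "Right"),
                                 sampling_rate = 200, rest_duration_s = 120,
                                 include_rest = TRUE) {
  plan <- list()
  if (include_rest) {
    plan$rest <- run_spec("rest", sampling_rate = sampling_rate,
                          duration_s = rest_duration_s)
  }
  for (i in 1:3) {
    plan[[paste0("MI-Cb", i)]] <- run_spec("MI-Cb", n_trials_per_class = 25,
                                           sampling_rate = sampling_rate)
  }
  for (i in 1:3) {
    plan[[paste0("MI-Fb", i)]] <- run_spec("MI-Fb", n_trials_per_class = 50,
                                           classes = feedback_classes,
                                           sampling_rate = sampling_rate)
  }
  plan
}
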