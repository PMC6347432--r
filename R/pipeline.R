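# Orchestration: calibration training with class-pair selection, user
# categorization, cohort-level summaries and group maps.

canonical_pairs <- function() {
  list("Left/Right" = c("Left", "Right"),
       "Left/Foot" = c("Left", "Foot"),
       "Foot/Right" = c("Foot", "Right"))
}

#' Train the calibration chain and select the class pair
#'
#' Applies artifact rejection once to the pooled calibration trials, then for
#' each two-class combination (Left/Right, Left/Foot, Foot/Right) selects the
#' subject-specific band and time interval, fits CSP, extracts log-variance
#' features, and computes two 8-fold cross-validated accuracies: the
#' optimistic "global" one (CSP fitted on all trials, outside the CV) and the
#' "generalization" one (CSP refitted inside each training fold). The pair
#' with the best generalization accuracy is selected (ties resolve in the
#' canonical order above) and its full chain is frozen: band/interval, CSP
#' filters fitted on all trials of the pair, and shrinkage LDA.
#'
#' @param calibration_runs List of raw `eeg_epochs` (one per calibration run,
#'   epoched around the stimulus, e.g. interval `c(-2, 6)`), or a list of
#'   `eeg_recording`s, which are epoched internally.
#' @param montage A `bci_montage`.
#' @param k CV folds (default 8).
#' @param n_per_class CSP filters per class (default 3, i.e. six filters).
#' @param seed Seed for the CV fold assignment.
#' @return An object of class `trained_system`: `class_pair`, `band_interval`,
#'   `csp`, `lda`, `global_acc` and `generalization_acc` (named per pair,
#'   AUC fractions), `clean_report`, `smr_channel`.
#' @export
train_bbci <- function(calibration_runs, montage, k = 8, n_per_class = 3, seed = 1,
                       epoch_interval = c(-2, 6), broad_band = c(8, 32)) {
  if (inherits(calibration_runs, "eeg_epochs") ||
      inherits(calibration_runs, "eeg_recording")) {
    calibration_runs <- list(calibration_runs)
  }
  is_rec <- vapply(calibration_runs, inherits, TRUE, "eeg_recording")
  # band-pass filtering is applied to the continuous signal where available
  # (no trial-edge transients, and one filter pass serves all class pairs)
  if (all(is_rec)) {
    raw_eps <- lapply(calibration_runs, epoch, epoch_interval)
    filter_pooled <- function(band) {
      pool_epochs(lapply(calibration_runs, function(r) {
        e <- epoch(bandpass(r, band), epoch_interval)
        e$band <- band
        e
      }))
    }
  } else {
    raw_eps <- lapply(calibration_runs, function(r) {
      if (inherits(r, "eeg_recording")) epoch(r, epoch_interval) else r
    })
    filter_pooled <- function(band) bandpass(pool_epochs(raw_eps), band)
  }
  pooled <- pool_epochs(raw_eps)
  cleaned <- clean(pooled, montage)
  ep <- cleaned$epochs
  keep_tr <- cleaned$report$kept_index
  keep_ch <- ep$channels
  band_cache <- new.env(parent = emptyenv())
  get_filtered <- function(band, trials) {
    key <- paste(round(band, 3), collapse = "_")
    if (is.null(band_cache[[key]])) band_cache[[key]] <- filter_pooled(band)
    subset_epochs(band_cache[[key]], trials = keep_tr[trials], channels = keep_ch)
  }
  classes_present <- unique(as.character(ep$labels))
  if (length(classes_present) < 2) stopf("need at least 2 classes across runs")

  pairs <- Filter(function(p) all(p %in% classes_present), canonical_pairs())
  if (!length(pairs)) stopf("no evaluable class pair among: %s",
                            paste(classes_present, collapse = ", "))
  global_acc <- gen_acc <- stats::setNames(rep(NA_real_, length(pairs)), names(pairs))
  fits <- list()
  diagnostics <- list()
  for (nm in names(pairs)) {
    pr <- pairs[[nm]]
    idx <- which(ep$labels %in% pr)
    res <- try({
      ti1 <- select_time_interval(get_filtered(broad_band, idx), montage)
      seg <- segment_epochs(subset_epochs(ep, trials = idx),
                            ti1[1] / 1000, ti1[2] / 1000)
      band <- select_frequency_band(seg, montage)
      narrow <- get_filtered(band, idx)
      ti2 <- select_time_interval(narrow, montage)
      bi <- band_interval(band[1], band[2], ti2[1], ti2[2],
                          low_confidence = isTRUE(attr(ti1, "low_confidence")) ||
                            isTRUE(attr(band, "low_confidence")) ||
                            isTRUE(attr(ti2, "low_confidence")))
      # CSP and classification operate on the motor-area channels
      prep <- subset_epochs(segment_epochs(narrow, bi$t_start / 1000, bi$t_end / 1000),
                            channels = intersect(motor_channels(montage), keep_ch))
      glob <- cross_validate(prep, "kfold", k = k, csp_scope = "global",
                             n_per_class = n_per_class, seed = seed)
      gen <- cross_validate(prep, "kfold", k = k, csp_scope = "per_fold",
                            n_per_class = n_per_class, seed = seed)
      list(bi = bi, prep = prep, narrow = narrow, glob = glob$auc, gen = gen$auc)
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      diagnostics[[nm]] <- attr(res, "condition")$message
      next
    }
    global_acc[nm] <- res$glob
    gen_acc[nm] <- res$gen
    fits[[nm]] <- res
  }
  if (!length(fits)) {
    stopf("calibration degenerate for all class pairs: %s",
          paste(sprintf("%s: %s", names(diagnostics), unlist(diagnostics)),
                collapse = "; "))
  }
  best <- names(fits)[which.max(gen_acc[names(fits)])]  # ties: canonical order
  bf <- fits[[best]]
  model <- fit_csp(class_covariances(bf$prep))
  feats <- select_and_extract(model, bf$prep, n_per_class)
  model <- attr(feats, "model")
  model$band_interval <- bf$bi
  lda <- fit_slda(feats, bf$prep$labels)
  smr_ch <- smr_channel_core(bf$narrow, bf$bi, montage)
  structure(list(class_pair = pairs[[best]], pair_label = best,
                 band_interval = bf$bi, csp = model, lda = lda,
                 global_acc = global_acc, generalization_acc = gen_acc,
                 smr_channel = as.character(smr_ch),
                 smr_channel_map = attr(smr_ch, "r2"),
                 clean_report = cleaned$report),
            class = "trained_system")
}

#' @export
print.trained_system <- function(x, ...) {
  cat(sprintf("<trained_system> pair %s, band %.1f-%.1f Hz, interval %d-%d ms\n",
              x$pair_label, x$band_interval$f_lo, x$band_interval$f_hi,
              round(x$band_interval$t_start), round(x$band_interval$t_end)))
  acc <- rbind(global = x$global_acc, generalization = x$generalization_acc)
  print(round(acc, 3))
  cat(sprintf("  SMR-channel: %s; CSP components: %s; LDA lambda %.3f\n",
              x$smr_channel, paste(x$csp$selected, collapse = ","),
              x$lda$shrink_lambda))
  invisible(x)
}

#' Categorize a user from calibration and feedback performance
#'
#' The 70% criterion defines the three main categories: I (calibration and
#' feedback >= 70%), II (calibration >= 70%, feedback < 70%), III
#' (calibration < 70%). Subflags: `"a"` for category I with feedback >= 90%,
#' `"c"` when performance dropped by at least 10 points from calibration to a
#' feedback level still >= 70%, `"b"` otherwise. With feedback performance
#' missing, calibration < 70% still yields III; otherwise the category is
#' flagged incomplete.
#'
#' @param cb_perf Calibration performance in percent (0-100).
#' @param fb_perf Feedback performance in percent, or NA.
#' @param threshold Main criterion (default 70).
#' @param strong_threshold Subflag-a criterion (default 90).
#' @return List with `category` ("I", "II", "III" or NA) and `subflag`.
#' @examples
#' categorize_user(90.99, 85.60) # category I
#' @export
categorize_user <- function(cb_perf, fb_perf = NA, threshold = 70,
                            strong_threshold = 90) {
  if (cb_perf < 0 || cb_perf > 100 || (!is.na(fb_perf) && (fb_perf < 0 || fb_perf > 100))) {
    stopf("performances must be within [0, 100]")
  }
  if (is.na(fb_perf)) {
    if (cb_perf < threshold) {
      return(list(category = "III", subflag = NA_character_, incomplete = TRUE))
    }
    return(list(category = NA_character_, subflag = NA_character_, incomplete = TRUE))
  }
  category <- if (cb_perf < threshold) "III"
              else if (fb_perf >= threshold) "I" else "II"
  subflag <- if (category == "I" && fb_perf >= strong_threshold) "a"
             else if (cb_perf - fb_perf >= 10 && fb_perf >= threshold) "c"
             else "b"
  list(category = category, subflag = subflag, incomplete = FALSE)
}

#' Summarize a cohort of categorized users
#'
#' Counts and percentages per category, class-pair tallies, and mean +- sd of
#' calibration and feedback performance per category and overall.
#'
#' @param reports Either a character vector of categories, or a data frame /
#'   list of per-user entries with fields `category` and optionally `cb_perf`,
#'   `fb_perf`, `class_pair`, `predictor_value`.
#' @return An object of class `category_report` with `table` (per category:
#'   n, percent, performance summaries), `n_users`, `pair_table`.
#' @export
summarize_categories <- function(reports) {
  if (is.character(reports)) {
    df <- data.frame(category = reports, stringsAsFactors = FALSE)
  } else if (is.data.frame(reports)) {
    df <- reports
  } else {
    df <- do.call(rbind, lapply(reports, function(r) {
      data.frame(category = r$category,
                 cb_perf = if (!is.null(r$cb_perf)) r$cb_perf else NA_real_,
                 fb_perf = if (!is.null(r$fb_perf)) r$fb_perf else NA_real_,
                 class_pair = if (!is.null(r$class_pair)) paste(r$class_pair, collapse = "/")
                              else NA_character_,
                 stringsAsFactors = FALSE)
    }))
  }
  if (!nrow(df)) stopf("no users to summarize")
  cats <- c("I", "II", "III")
  n_users <- nrow(df)
  rows <- lapply(cats, function(cc) {
    sub <- df[df$category %in% cc, , drop = FALSE]
    data.frame(category = cc, n = nrow(sub),
               percent = format_percent(nrow(sub), n_users),
               cb_mean = if (!is.null(sub$cb_perf)) mean(sub$cb_perf) else NA_real_,
               cb_sd = if (!is.null(sub$cb_perf)) stats::sd(sub$cb_perf) else NA_real_,
               fb_mean = if (!is.null(sub$fb_perf)) mean(sub$fb_perf) else NA_real_,
               fb_sd = if (!is.null(sub$fb_perf)) stats::sd(sub$fb_perf) else NA_real_)
  })
  tab <- do.call(rbind, rows)
  pair_tab <- if (!is.null(df$class_pair)) table(df$category, df$class_pair) else NULL
  structure(list(table = tab, n_users = n_users, pair_table = pair_tab,
                 overall = data.frame(
                   cb_mean = if (!is.null(df$cb_perf)) mean(df$cb_perf) else NA_real_,
                   cb_sd = if (!is.null(df$cb_perf)) stats::sd(df$cb_perf) else NA_real_,
                   fb_mean = if (!is.null(df$fb_perf)) mean(df$fb_perf) else NA_real_,
                   fb_sd = if (!is.null(df$fb_perf)) stats::sd(df$fb_perf) else NA_real_)),
            class = "category_report")
}

#' @export
print.category_report <- function(x, ...) {
  cat(sprintf("<category_report> %d users\n", x$n_users))
  tab <- x$table
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  Cat %-3s %3d (%5.1f%%)", tab$category[i], tab$n[i], tab$percent[i]))
    if (!is.na(tab$cb_mean[i])) {
      cat(sprintf("  Cb %5.2f +- %5.2f  Fb %5.2f +- %5.2f",
                  tab$cb_mean[i], tab$cb_sd[i], tab$fb_mean[i], tab$fb_sd[i]))
    }
    cat("\n")
  }
  invisible(x)
}

#' Group-level maps across users
#'
#' Builds the reactive-band histogram (per frequency bin, the number of users
#' whose selected band covers the bin), the grand-average z map (mean of
#' per-user z maps with a significance mask at `|z| >= -ln(0.05) = 2.9957`),
#' and the SMR-channel selection counts.
#'
#' @param users List of per-user entries with `band` (`c(f_lo, f_hi)` Hz),
#'   `z_map` (named numeric per channel), `smr_channel`.
#' @param freq_grid Histogram grid in Hz (default 5-35 by 1).
#' @param p Significance level for the mask (default 0.05).
#' @return List with `band_histogram` (data frame freq/count),
#'   `grand_average_z` (named numeric), `significance_mask` (named logical),
#'   `smr_channel_counts` (table).
#' @export
group_maps <- function(users, freq_grid = seq(5, 35, by = 1), p = 0.05) {
  counts <- vapply(freq_grid, function(f0) {
    sum(vapply(users, function(u) f0 >= u$band[1] && f0 <= u$band[2], TRUE))
  }, 0L)
  zmaps <- lapply(users, `[[`, "z_map")
  chans <- names(zmaps[[1]])
  zmat <- do.call(rbind, lapply(zmaps, function(z) z[chans]))
  gz <- colMeans(zmat)
  thr <- significance_threshold(p)
  list(band_histogram = data.frame(freq = freq_grid, count = counts),
       grand_average_z = gz,
       significance_mask = abs(gz) >= thr,
       smr_channel_counts = table(vapply(users, `[[`, "", "smr_channel")))
}

#' Cluster users by reactive-band center and compare performance
#'
#' Two-cluster k-means (10 restarts, seeded) on the band centers, followed by
#' a one-tailed rank-sum test of the hypothesis that the lower-frequency
#' (mu-band) cluster performs better than the higher-frequency (beta-band)
#' cluster during feedback.
#'
#' @param band_centers Per-user band center in Hz (e.g. band midpoint).
#' @param fb_perfs Per-user feedback performance in percent.
#' @param seed Seed for the k-means restarts.
#' @return List with `assignments` (1 = lower cluster), `centers` (sorted
#'   ascending), `medians` (per cluster feedback-performance medians) and
#'   `test_p` (one-tailed Wilcoxon rank-sum p-value).
#' @export
cluster_bands <- function(band_centers, fb_perfs, seed = 1) {
  if (length(band_centers) < 2 || length(unique(band_centers)) < 2) {
    stopf("need at least two distinct band centers to cluster")
  }
  stopifnot(length(band_centers) == length(fb_perfs))
  km <- with_local_seed(seed, stats::kmeans(matrix(band_centers), centers = 2,
                                            nstart = 10))
  ord <- order(km$centers)
  assign <- match(km$cluster, ord)  # 1 = lower-frequency cluster
  lowp <- fb_perfs[assign == 1]; highp <- fb_perfs[assign == 2]
  pv <- stats::wilcox.test(lowp, highp, alternative = "greater", exact = FALSE)$p.value
  list(assignments = assign, centers = sort(as.vector(km$centers)),
       medians = c(lower = stats::median(lowp), higher = stats::median(highp)),
       test_p = pv)
}

#' Full screening analysis of one simulated user
#'
#' End-to-end pipeline: simulate rest plus three calibration runs, train the
#' calibration chain (class-pair selection included), simulate three feedback
#' runs with the chosen pair (applying the profile's feedback drift), replay
#' them through the online classifier with bias adaptation, compute the
#' rest-spectrum SMR predictor, and categorize the user.
#'
#' @param profile A [make_user_profile()] object.
#' @param montage A `bci_montage`.
#' @param seed Master seed (default: profile seed).
#' @param fs Sampling rate in Hz.
#' @param rest_duration_s Rest recording length.
#' @param n_feedback_runs Number of feedback runs (default 3).
#' @return List (class `user_report`): `category`, `subflag`, `cb_perf`,
#'   `fb_perf` (percent), `fb_runs` (per-run hit rates), `class_pair`,
#'   `band_interval`, `smr_channel`, `predictor_value`, `expected_control`,
#'   `trained`, `truth` (the profile template).
#' @export
analyze_user <- function(profile, montage = make_montage(), seed = profile$seed,
                         fs = 200, rest_duration_s = 120, n_feedback_runs = 3) {
  rest <- simulate_rest(profile, rest_duration_s, montage,
                        seed = derive_seed(seed, "rest"), fs = fs)
  cal_runs <- lapply(1:3, function(i) {
    simulate_run(profile, run_spec("MI-Cb", 25, sampling_rate = fs), montage,
                 seed = derive_seed(seed, paste0("cb", i)))
  })
  trained <- train_bbci(cal_runs, montage, seed = derive_seed(seed, "cv"),
                        epoch_interval = c(-1, 5.5))
  cb_perf <- 100 * max(trained$generalization_acc, na.rm = TRUE)

  fb_hits <- numeric(n_feedback_runs)
  for (j in seq_len(n_feedback_runs)) {
    fb <- simulate_run(profile,
                       run_spec("MI-Fb", 50, classes = trained$class_pair,
                                sampling_rate = fs),
                       montage, seed = derive_seed(seed, paste0("fb", j)),
                       depth_scale = profile$drift^j)
    res <- simulate_feedback(fb, trained$band_interval, trained$csp, trained$lda)
    fb_hits[j] <- res$hit_rate
  }
  fb_perf <- 100 * mean(fb_hits)
  pred <- compute_predictor(rest, montage)
  cat_res <- categorize_user(cb_perf, fb_perf)
  structure(list(category = cat_res$category, subflag = cat_res$subflag,
                 cb_perf = cb_perf, fb_perf = fb_perf, fb_runs = 100 * fb_hits,
                 class_pair = trained$class_pair, pair_label = trained$pair_label,
                 band_interval = trained$band_interval,
                 smr_channel = trained$smr_channel,
                 predictor_value = pred$value,
                 expected_control = predict_control(pred$value),
                 trained = trained,
                 truth = profile$category_template, seed = seed),
            class = "user_report")
}

#' @export
print.user_report <- function(x, ...) {
  cat(sprintf("<user_report> Cat %s%s (truth %s): Cb %.1f%%, Fb %.1f%%, pair %s, predictor %.2f dB\n",
              x$category, ifelse(is.na(x$subflag), "", x$subflag), x$truth,
              x$cb_perf, x$fb_perf, x$pair_label, x$predictor_value))
  invisible(x)
}

#' Analyze a simulated cohort
#'
#' Runs [analyze_user()] for each profile and summarizes the categorization.
#'
#' @param profiles List of [make_user_profile()] objects.
#' @param montage A `bci_montage`.
#' @param seed Master seed; user i runs with a seed derived from it.
#' @param ... Passed to [analyze_user()].
#' @return List with `users` (list of `user_report`), `summary`
#'   (a `category_report`) and `recovery` (fraction of users whose assigned
#'   main category matches their generating template).
#' @export
run_cohort <- function(profiles, montage = make_montage(), seed = 1, ...) {
  users <- vector("list", length(profiles))
  for (i in seq_along(profiles)) {
    users[[i]] <- analyze_user(profiles[[i]], montage,
                               seed = derive_seed(seed, paste0("user", i)), ...)
  }
  df <- data.frame(category = vapply(users, `[[`, "", "category"),
                   cb_perf = vapply(users, `[[`, 0, "cb_perf"),
                   fb_perf = vapply(users, `[[`, 0, "fb_perf"),
                   class_pair = vapply(users, `[[`, "", "pair_label"),
                   truth = vapply(users, `[[`, "", "truth"),
                   stringsAsFactors = FALSE)
  list(users = users, summary = summarize_categories(df),
       recovery = mean(df$category == df$truth), table = df)
}
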