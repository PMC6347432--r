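# Shrinkage LDA, AUC scoring, cross-validation schemes, transfer evaluation
# and online feedback simulation.

#' Fit a shrinkage LDA classifier
#'
#' Linear discriminant `w = Sigma_lambda^-1 (mu2 - mu1)` with the pooled
#' within-class covariance shrunk toward the restricted sub-model in which all
#' variances are equal and all covariances zero: `Sigma_lambda =
#' (1-lambda) Sigma + lambda * nu * I`, `nu` the mean sample variance. The
#' shrinkage intensity is estimated analytically (Ledoit-Wolf /
#' Schaefer-Strimmer) and clipped to `[0, 1]`, which keeps the fit
#' well-defined even with more features than trials. The bias is the midpoint
#' rule `b = -w'(mu1 + mu2)/2`, so scores are positive for class 2.
#'
#' @param features Trials x features matrix.
#' @param labels Class label per trial (two classes).
#' @param lambda Optional fixed shrinkage intensity; default: analytic.
#' @param classes Optional length-2 class order (class 1, class 2).
#' @return Object of class `slda`: `w`, `b`, `shrink_lambda`, `class_order`,
#'   `means`.
#' @export
fit_slda <- function(features, labels, lambda = NULL, classes = NULL) {
  features <- as.matrix(features)
  if (is.null(classes)) classes <- sort(unique(as.character(labels)))
  if (length(classes) < 2) stopf("need two classes to fit a discriminant")
  labels <- as.character(labels)
  i1 <- labels == classes[1]; i2 <- labels == classes[2]
  if (sum(i1) < 2 || sum(i2) < 2) stopf("need >= 2 trials per class")
  mu1 <- colMeans(features[i1, , drop = FALSE])
  mu2 <- colMeans(features[i2, , drop = FALSE])
  Xc <- rbind(sweep(features[i1, , drop = FALSE], 2, mu1),
              sweep(features[i2, , drop = FALSE], 2, mu2))
  n <- nrow(Xc); p <- ncol(Xc)
  S <- crossprod(Xc) / (n - 1)
  nu <- mean(diag(S))
  if (is.null(lambda)) {
    # analytic intensity toward nu*I (Schaefer-Strimmer form)
    wbar <- crossprod(Xc) / n
    num <- 0
    for (k in seq_len(n)) {
      Wk <- tcrossprod(Xc[k, ])
      num <- num + sum((Wk - wbar)^2)
    }
    varS <- n / (n - 1)^3 * num
    target <- diag(nu, p)
    den <- sum((S - target)^2)
    lambda <- if (den > 0) varS / den else 1
    lambda <- min(max(lambda, 0), 1)
  }
  Slam <- (1 - lambda) * S + lambda * diag(nu, p)
  w <- solve(Slam, mu2 - mu1)
  b <- -sum(w * (mu1 + mu2)) / 2
  structure(list(w = w, b = b, shrink_lambda = lambda,
                 class_order = classes[1:2], means = rbind(mu1, mu2)),
            class = "slda")
}

#' @export
print.slda <- function(x, ...) {
  cat(sprintf("<slda> %d features, lambda = %.3f; %s (neg) vs %s (pos)\n",
              length(x$w), x$shrink_lambda, x$class_order[1], x$class_order[2]))
  invisible(x)
}

#' @export
coef.slda <- function(object, ...) c(object$w, bias = object$b)

#' Classifier scores
#'
#' `score = w'x + b`; positive scores vote for the second class of
#' `class_order`, negative for the first.
#'
#' @param model An `slda` object.
#' @param features Trials x features matrix (or vector for one trial).
#' @return Numeric score per trial.
#' @export
decide <- function(model, features) {
  features <- if (is.null(dim(features))) matrix(features, nrow = 1)
              else as.matrix(features)
  if (ncol(features) != length(model$w)) {
    stopf("feature dimension %d does not match model (%d)",
          ncol(features), length(model$w))
  }
  drop(features %*% model$w + model$b)
}

#' @export
predict.slda <- function(object, newdata, type = c("score", "class"), ...) {
  s <- decide(object, newdata)
  if (match.arg(type) == "score") return(s)
  object$class_order[ifelse(s > 0, 2L, 1L)]
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a class-2 trial scores
#' higher than a class-1 trial, ties counted 1/2.
#'
#' @param scores Per-trial scores (higher = more class-2).
#' @param labels Class label per trial.
#' @param classes Optional class order (class 1 first).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels, classes = NULL) {
  if (is.null(classes)) classes <- sort(unique(as.character(labels)))
  if (length(classes) != 2) stopf("both classes must be present for AUC")
  labels <- as.character(labels)
  i2 <- labels == classes[2]
  n1 <- sum(!i2); n2 <- sum(i2)
  if (n1 == 0 || n2 == 0) stopf("both classes must be present for AUC")
  r <- rank(scores)
  (sum(r[i2]) - n2 * (n2 + 1) / 2) / (n1 * n2)
}

new_eval_result <- function(scheme, auc, hit_rate = NA_real_, n_train = NA_integer_,
                            n_test = NA_integer_, per_run = NULL, extra = NULL) {
  structure(c(list(scheme = scheme, auc = auc, hit_rate = hit_rate,
                   n_train = n_train, n_test = n_test, per_run = per_run), extra),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> %s: AUC %.3f%s (n_train %s, n_test %s)\n",
              x$scheme, x$auc,
              if (!is.na(x$hit_rate)) sprintf(", hit rate %.3f", x$hit_rate) else "",
              x$n_train, x$n_test))
  invisible(x)
}

# stratified fold assignment
stratified_folds <- function(labels, k, seed = 1) {
  with_local_seed(seed, {
    fold <- integer(length(labels))
    for (cls in unique(labels)) {
      idx <- sample(which(labels == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' Cross-validated classification accuracy of CSP + shrinkage LDA
#'
#' `csp_scope = "global"` fits the CSP filters once on all trials and
#' cross-validates only the LDA (the in-sample, optimistic "global" figure);
#' `"per_fold"` refits CSP and LDA inside each training fold (the
#' "generalization" figure). Folds are stratified by class; the reported AUC
#' pools the held-out scores of all folds. The subject-specific band and
#' interval are inputs (the epochs are expected band-filtered and segmented)
#' and are not re-selected per fold.
#'
#' @param epochs Band-filtered, segmented `eeg_epochs`, two classes.
#' @param scheme `"kfold"` (default, `k` folds), `"loo"`, or `"twofold"`.
#' @param k Folds for `"kfold"` (default 8).
#' @param csp_scope `"per_fold"` (default) or `"global"`.
#' @param n_per_class CSP filters per class (see [select_and_extract()]).
#' @param seed Seed for the stratified fold assignment.
#' @return An `eval_result` with pooled `auc` and sign-based `hit_rate`.
#' @export
cross_validate <- function(epochs, scheme = c("kfold", "loo", "twofold"), k = 8,
                           csp_scope = c("per_fold", "global"), n_per_class = 3,
                           seed = 1) {
  scheme <- match.arg(scheme)
  csp_scope <- match.arg(csp_scope)
  classes <- sort(unique(as.character(epochs$labels)))
  stopifnot(length(classes) == 2)
  n <- dim(epochs$data)[1]
  k_eff <- switch(scheme, kfold = k, loo = n, twofold = 2)
  if (n < k_eff) stopf("fewer trials (%d) than folds (%d)", n, k_eff)
  fold <- if (scheme == "loo") seq_len(n) else stratified_folds(epochs$labels, k_eff, seed)

  scores <- numeric(n)
  if (csp_scope == "global") {
    model <- fit_csp(class_covariances(epochs, classes))
    feats <- select_and_extract(model, epochs, n_per_class)
    for (f in seq_len(k_eff)) {
      tr <- fold != f; te <- !tr
      lda <- fit_slda(feats[tr, , drop = FALSE], epochs$labels[tr], classes = classes)
      scores[te] <- decide(lda, feats[te, , drop = FALSE])
    }
  } else {
    tc <- trial_covs(epochs)  # per-trial covariances shared across folds
    for (f in seq_len(k_eff)) {
      tr <- which(fold != f); te <- which(fold == f)
      labs_tr <- epochs$labels[tr]
      if (length(unique(labs_tr)) < 2) {
        stopf("fold %d lost a class; use fewer folds", f)
      }
      s1 <- avg_trial_cov(tc, tr[labs_tr == classes[1]], epochs$channels)
      s2 <- avg_trial_cov(tc, tr[labs_tr == classes[2]], epochs$channels)
      model <- fit_csp(s1, s2, classes = classes)
      bp <- csp_band_power(model, epochs)
      sel <- select_components_core(model, bp[tr, , drop = FALSE], labs_tr,
                                    classes, n_per_class)
      feats <- log(bp[, sel$selected, drop = FALSE])
      lda <- fit_slda(feats[tr, , drop = FALSE], labs_tr, classes = classes)
      scores[te] <- decide(lda, feats[te, , drop = FALSE])
    }
  }
  hits <- (scores > 0) == (epochs$labels == classes[2])
  new_eval_result(paste0(scheme, "-", csp_scope), auc(scores, epochs$labels, classes),
                  hit_rate = mean(hits),
                  n_train = n - ceiling(n / k_eff), n_test = n,
                  extra = list(scores = scores, classes = classes))
}

#' Transfer evaluation with frozen parameters
#'
#' Applies a frozen chain (band/interval, CSP, LDA) to a test run: the test
#' epochs are band-pass filtered and segmented with the trained band and
#' interval, projected through the trained CSP filters, and scored by the
#' trained LDA. When `csp` / `lda` are omitted they are (re)fitted on the
#' pooled training runs, the procedure used for calibration runs where the
#' evaluated run is excluded from its own training set.
#'
#' @param train_runs List of raw `eeg_epochs` used for (re)fitting.
#' @param test_run Raw `eeg_epochs` to evaluate.
#' @param bi A [band_interval()] (frozen subject-specific parameters).
#' @param csp,lda Optional pre-trained `csp` model (with `selected`) and
#'   `slda`; refitted from `train_runs` when NULL.
#' @param n_per_class CSP filters per class when refitting.
#' @return An `eval_result` (`scheme = "transfer"`).
#' @export
transfer_evaluate <- function(train_runs, test_run, bi, csp = NULL, lda = NULL,
                              n_per_class = 3) {
  prep <- function(e) {
    segment_epochs(bandpass(e, c(bi$f_lo, bi$f_hi)), bi$t_start / 1000, bi$t_end / 1000)
  }
  if (is.null(csp) || is.null(lda)) {
    pool <- pool_epochs(lapply(train_runs, prep))
    classes <- sort(unique(as.character(pool$labels)))
    model <- fit_csp(class_covariances(pool, classes))
    ftr <- select_and_extract(model, pool, n_per_class)
    csp <- attr(ftr, "model")
    lda <- fit_slda(ftr, pool$labels, classes = classes)
    n_train <- dim(pool$data)[1]
  } else {
    n_train <- NA_integer_
  }
  te <- prep(test_run)
  fte <- log(csp_band_power(csp, te, components = csp$selected))
  scores <- decide(lda, fte)
  classes <- lda$class_order
  hits <- (scores > 0) == (te$labels == classes[2])
  new_eval_result("transfer", auc(scores, te$labels, classes),
                  hit_rate = mean(hits), n_train = n_train,
                  n_test = dim(te$data)[1], extra = list(scores = scores))
}

# concatenate epoch sets (same channels/time grid)
pool_epochs <- function(epoch_list) {
  e1 <- epoch_list[[1]]
  if (length(epoch_list) == 1) return(e1)
  nt <- vapply(epoch_list, function(e) dim(e$data)[1], 0L)
  d <- dim(e1$data)
  data <- array(0, c(sum(nt), d[2], d[3]))
  labels <- character(0)
  at <- 0
  for (e in epoch_list) {
    k <- dim(e$data)[1]
    data[at + seq_len(k), , ] <- e$data
    labels <- c(labels, as.character(e$labels))
    at <- at + k
  }
  new_epochs(data, e1$time, labels, e1$fs, e1$channels, band = e1$band)
}

#' Simulate online feedback classification
#'
#' Replays a feedback run through a frozen chain the way the online system
#' works: the whole 4 s activity period is classified with sliding
#' log-variance windows (no subject-specific time interval), the cursor is the
#' cumulative sum of the classifier scores, and a trial is a hit when the sign
#' of the final cursor position matches the target class. After the first
#' `adapt_bias_after` trials the bias is re-centered by subtracting the mean
#' window score observed over those trials; the hit rate is reported over the
#' remaining trials (100-trial runs with the default 20 give 80 scored
#' trials).
#'
#' @param run An `eeg_recording` of a feedback run (markers present).
#' @param bi A [band_interval()] (only the band is used online).
#' @param csp Trained `csp` model with `selected` components.
#' @param lda Trained `slda`.
#' @param adapt_bias_after Trials used for bias adaptation (default 20; 0
#'   disables adaptation).
#' @param activity_window `(t0, t1)` seconds after the stimulus classified
#'   online (default `c(0, 4)`).
#' @param window_s,step_s Sliding-window length and step in seconds.
#' @return An `eval_result` (`scheme = "online"`): `hit_rate` over the scored
#'   trials, `auc` of the final cursor positions, `extra$cursor` final cursor
#'   per trial, `extra$bias_offset`.
#' @export
simulate_feedback <- function(run, bi, csp, lda, adapt_bias_after = 20,
                              activity_window = c(0, 4),
                              window_s = 0.75, step_s = 0.04) {
  if (is.null(run$markers) || nrow(run$markers) == 0) {
    stopf("feedback run has no markers")
  }
  filt <- bandpass(run, c(bi$f_lo, bi$f_hi))
  ep <- epoch(filt, activity_window)
  fs <- ep$fs
  d <- dim(ep$data)
  L <- round(window_s * fs)
  step <- max(1, round(step_s * fs))
  starts <- seq(1, d[3] - L + 1, by = step)
  W <- csp$filters[, csp$selected, drop = FALSE]
  ci <- if (!is.null(rownames(csp$filters))) {
    match(rownames(csp$filters), ep$channels)
  } else {
    seq_len(d[2])
  }
  if (anyNA(ci)) stopf("feedback run lacks CSP model channel(s)")
  classes <- lda$class_order
  n_tr <- d[1]
  trial_scores <- vector("list", n_tr)
  for (tr in seq_len(n_tr)) {
    S <- crossprod(W, matrix(ep$data[tr, ci, ], length(ci), d[3]))  # comps x time
    cs1 <- cbind(0, t(apply(S, 1, cumsum)))
    cs2 <- cbind(0, t(apply(S^2, 1, cumsum)))
    feats <- matrix(0, length(starts), nrow(S))
    for (wi in seq_along(starts)) {
      a <- starts[wi]; b2 <- a + L - 1
      s1 <- cs1[, b2 + 1] - cs1[, a]
      s2 <- cs2[, b2 + 1] - cs2[, a]
      feats[wi, ] <- log(pmax((s2 - s1^2 / L) / (L - 1), 1e-20))
    }
    trial_scores[[tr]] <- decide(lda, feats)
  }
  offset <- 0
  n_adapt <- min(adapt_bias_after, n_tr)
  if (n_adapt > 0 && n_adapt < n_tr) {
    offset <- mean(unlist(trial_scores[seq_len(n_adapt)]))
  }
  scored <- if (n_adapt < n_tr) (n_adapt + 1):n_tr else seq_len(n_tr)
  cursor <- vapply(seq_len(n_tr), function(tr) sum(trial_scores[[tr]] - offset), 0)
  labels <- ep$labels
  hits <- (cursor[scored] > 0) == (labels[scored] == classes[2])
  new_eval_result("online",
                  auc = auc(cursor[scored], labels[scored], classes),
                  hit_rate = mean(hits), n_train = n_adapt,
                  n_test = length(scored),
                  extra = list(cursor = cursor, bias_offset = offset,
                               labels = labels))
}
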