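# Shrinkage LDA, AUC, cross-validation, transfer and online simulation.

make_gauss_features <- function(n_per_class, mu_diff, p = 2, seed = 1, sigma = NULL) {
  smrbci:::with_local_seed(seed, {
    if (is.null(sigma)) sigma <- diag(p)
    L <- chol(sigma)
    X1 <- matrix(rnorm(n_per_class * p), n_per_class) %*% L
    X2 <- sweep(matrix(rnorm(n_per_class * p), n_per_class) %*% L, 2, -mu_diff)
    list(X = rbind(X1, X2), y = rep(c("c1", "c2"), each = n_per_class))
  })
}

test_that("shrinkage limits reproduce the mean-difference and plain LDA solutions", {
  g <- make_gauss_features(40, c(2, 0.5, -1), p = 3, seed = 41)
  # lambda = 1: w proportional to mu2 - mu1
  m1 <- fit_slda(g$X, g$y, lambda = 1)
  mu1 <- colMeans(g$X[g$y == "c1", ]); mu2 <- colMeans(g$X[g$y == "c2", ])
  expect_equal(abs(cor(m1$w, mu2 - mu1)), 1, tolerance = 1e-10)
  # lambda = 0: plain LDA closed form on well-conditioned data
  m0 <- fit_slda(g$X, g$y, lambda = 0)
  Xc <- rbind(sweep(g$X[g$y == "c1", ], 2, mu1), sweep(g$X[g$y == "c2", ], 2, mu2))
  S <- crossprod(Xc) / (nrow(Xc) - 1)
  expect_equal(m0$w, solve(S, mu2 - mu1), tolerance = 1e-10)
  # analytic lambda lands inside [0, 1] and close to 0 for abundant data
  ma <- fit_slda(g$X, g$y)
  expect_gte(ma$shrink_lambda, 0); expect_lte(ma$shrink_lambda, 1)
})

test_that("the Bayes direction is recovered for identity covariance", {
  g <- make_gauss_features(600, c(2, 0), p = 2, seed = 42)
  m <- fit_slda(g$X, g$y)
  ang <- acos(abs(sum(m$w * c(1, 0))) / sqrt(sum(m$w^2))) * 180 / pi
  expect_lt(ang, 5)
})

test_that("shrinkage keeps the fit well-posed with more features than trials", {
  smrbci:::with_local_seed(43, {
    X <- matrix(rnorm(20 * 50), 20, 50)
  })
  y <- rep(c("a", "b"), 10)
  m <- fit_slda(X, y)
  expect_true(all(is.finite(m$w)))
  expect_gt(m$shrink_lambda, 0)
  expect_error(fit_slda(X[y == "a", ], y[y == "a"]), "class")
})

test_that("decision scores follow the midpoint-bias linear rule", {
  g <- make_gauss_features(50, c(3, 0), seed = 44)
  m <- fit_slda(g$X, g$y)
  mu1 <- colMeans(g$X[g$y == "c1", ]); mu2 <- colMeans(g$X[g$y == "c2", ])
  expect_lt(decide(m, mu1), 0)                      # class-1 centroid negative
  expect_gt(decide(m, mu2), 0)
  expect_equal(decide(m, (mu1 + mu2) / 2), 0, tolerance = 1e-10)
  # translation shifts scores by w' delta
  delta <- c(0.7, -0.2)
  s0 <- decide(m, g$X)
  s1 <- decide(m, sweep(g$X, 2, -delta))
  expect_equal(s1 - s0, rep(sum(m$w * delta), nrow(g$X)), tolerance = 1e-10)
  expect_error(decide(m, cbind(g$X, 0)), "dimension")
  expect_identical(predict(m, mu2, type = "class"), "c2")
})

test_that("AUC follows the Mann-Whitney count with ties at one half", {
  expect_equal(auc(c(1, 2, 3, 4), c(1, 1, 2, 2)), 1)
  expect_equal(auc(c(1, 3, 2, 4), c(1, 1, 2, 2)), 0.75)
  expect_equal(auc(rep(1, 10), rep(c("a", "b"), 5)), 0.5)
  # invariance under strictly monotone transforms
  set.seed(45)
  s <- rnorm(40); y <- sample(c("a", "b"), 40, replace = TRUE)
  if (length(unique(y)) == 2) {
    expect_equal(auc(exp(s), y), auc(s, y), tolerance = 1e-12)
    expect_equal(auc(5 * s - 2, y), auc(s, y), tolerance = 1e-12)
  }
  expect_error(auc(1:3, rep("a", 3)), "both classes")
})

test_that("cross-validation separates signal from label noise", {
  e <- make_var_epochs(n_per_class = 20, vars = list(c(4, 1, 1, 1), c(1, 4, 1, 1)),
                       nt = 300, seed = 46)
  cv <- cross_validate(e, "kfold", k = 8, csp_scope = "per_fold", seed = 1)
  expect_gt(cv$auc, 0.85)
  # shuffled labels: chance
  e0 <- e
  e0$labels <- smrbci:::with_local_seed(47, sample(e$labels))
  cv0 <- cross_validate(e0, "kfold", k = 8, csp_scope = "per_fold", seed = 1)
  expect_gt(cv0$auc, 0.3); expect_lt(cv0$auc, 0.7)
  # loo and twofold schemes run and report sensible sizes
  cvl <- cross_validate(e, "loo", csp_scope = "global", seed = 1)
  expect_gt(cvl$auc, 0.85)
  expect_equal(cvl$n_test, 40)
})

test_that("in-sample CSP (global) is optimistic relative to per-fold refits", {
  diffs <- vapply(1:10, function(s) {
    e <- make_var_epochs(n_per_class = 12,
                         vars = list(c(1.6, 1, 1, 1), c(1, 1.6, 1, 1)),
                         nt = 80, seed = 500 + s)
    g <- cross_validate(e, "kfold", k = 8, csp_scope = "global", seed = s)
    p <- cross_validate(e, "kfold", k = 8, csp_scope = "per_fold", seed = s)
    g$auc - p$auc
  }, 0)
  expect_gt(mean(diffs), 0)
})

test_that("transfer evaluation freezes parameters and tracks distribution shift", {
  mk <- function(seed, gap = 4) {
    make_var_epochs(n_per_class = 15, vars = list(c(gap, 1, 1), c(1, gap, 1)),
                    nt = 200, seed = seed, fs = 100)
  }
  train <- list(mk(61), mk(62))
  test_same <- mk(63)
  bi <- band_interval(8, 30, 0, 1990)
  res <- transfer_evaluate(train, test_same, bi)
  expect_gt(res$auc, 0.9)
  # in-sample evaluation is at least as good as held-out transfer on average
  res_in <- transfer_evaluate(train, train[[1]], bi)
  expect_gte(res_in$auc + 0.05, res$auc)
  # weakened test-run contrast (drifted patterns) lowers transfer accuracy
  test_weak <- mk(64, gap = 1.15)
  res_weak <- transfer_evaluate(train, test_weak, bi)
  expect_lt(res_weak$auc, res$auc)
})

test_that("online feedback replay scores trials by final cursor sign", {
  prof <- make_user_profile("I", seed = 71)
  mnt <- fix_montage
  cal <- simulate_run(prof, run_spec("MI-Cb", 12, classes = c("Left", "Right"),
                                     block_size = 2), mnt, seed = 72)
  ep <- epoch(cal, c(-1, 5.5))
  bi <- band_interval(prof$peak_params[["mu_alpha"]] - 2,
                      prof$peak_params[["mu_alpha"]] + 2, 500, 3800)
  prep <- smrbci:::segment_epochs(bandpass(ep, c(bi$f_lo, bi$f_hi)), 0.5, 3.8)
  prep <- smrbci:::subset_epochs(prep, channels = smrbci:::motor_channels(mnt))
  feats <- select_and_extract(fit_csp(class_covariances(prep)), prep, 3)
  csp <- attr(feats, "model")
  lda <- fit_slda(feats, prep$labels)
  fb <- simulate_run(prof, run_spec("MI-Fb", 15, classes = c("Left", "Right"),
                                    block_size = 10), mnt, seed = 73)
  res <- simulate_feedback(fb, bi, csp, lda, adapt_bias_after = 6)
  expect_equal(res$n_test, 24)
  expect_gt(res$hit_rate, 0.70)  # strong-SMR user reaches the control criterion
  # a flat user stays at chance when the chain is trained on a held-out run
  prof0 <- make_user_profile("III", seed = 74)
  prof0$erd_depth[] <- 0
  cal0 <- simulate_run(prof0, run_spec("MI-Cb", 15, classes = c("Left", "Right"),
                                       block_size = 6), mnt, seed = 76)
  prep0 <- epoch(bandpass(cal0, c(bi$f_lo, bi$f_hi)), c(0.5, 3.8))
  prep0 <- smrbci:::subset_epochs(prep0, channels = smrbci:::motor_channels(mnt))
  f0 <- select_and_extract(fit_csp(class_covariances(prep0)), prep0, 3)
  fb0 <- simulate_run(prof0, run_spec("MI-Fb", 15, classes = c("Left", "Right"),
                                      block_size = 10), mnt, seed = 75)
  res0 <- simulate_feedback(fb0, bi, attr(f0, "model"), fit_slda(f0, prep0$labels),
                            adapt_bias_after = 0)
  expect_gt(res0$hit_rate, 0.25); expect_lt(res0$hit_rate, 0.75)
  fb_nomark <- fb; fb_nomark$markers <- NULL
  expect_error(simulate_feedback(fb_nomark, bi, csp, lda), "markers")
})

test_that("bias adaptation recovers from a constant score offset", {
  prof <- make_user_profile("I", seed = 81)
  mnt <- fix_montage
  cal <- simulate_run(prof, run_spec("MI-Cb", 12, classes = c("Left", "Right"),
                                     block_size = 2), mnt, seed = 82)
  ep <- epoch(cal, c(-1, 5.5))
  bi <- band_interval(prof$peak_params[["mu_alpha"]] - 2,
                      prof$peak_params[["mu_alpha"]] + 2, 500, 3800)
  prep <- smrbci:::segment_epochs(bandpass(ep, c(bi$f_lo, bi$f_hi)), 0.5, 3.8)
  prep <- smrbci:::subset_epochs(prep, channels = smrbci:::motor_channels(mnt))
  feats <- select_and_extract(fit_csp(class_covariances(prep)), prep, 3)
  csp <- attr(feats, "model")
  lda <- fit_slda(feats, prep$labels)
  lda_bad <- lda
  lda_bad$b <- lda$b + 5 * sd(decide(lda, feats))  # contaminate the bias
  fb <- simulate_run(prof, run_spec("MI-Fb", 20, classes = c("Left", "Right"),
                                    block_size = 4), mnt, seed = 83)
  without <- simulate_feedback(fb, bi, csp, lda_bad, adapt_bias_after = 0)
  with_ad <- simulate_feedback(fb, bi, csp, lda_bad, adapt_bias_after = 10)
  expect_gt(with_ad$hit_rate, without$hit_rate)
  expect_gt(abs(with_ad$bias_offset), 0)
})
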