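# CSP estimation, scoring and feature extraction.

test_that("class covariances concentrate on the active channels", {
  e <- make_var_epochs(n_per_class = 15, vars = list(c(9, 1), c(1, 9)),
                       nt = 400, seed = 31)
  cc <- class_covariances(e)
  expect_equal(cc$sigma1, t(cc$sigma1), tolerance = 1e-12)
  expect_gt(cc$sigma1[1, 1], cc$sigma1[2, 2])  # class A power on channel 1
  expect_gt(cc$sigma2[2, 2], cc$sigma2[1, 1])
  # trace normalization: each class covariance has unit trace
  expect_equal(sum(diag(cc$sigma1)), 1, tolerance = 1e-12)
  e1 <- smrbci:::subset_epochs(e, trials = c(1, 16))
  expect_error(class_covariances(e1), ">= 2 trials")
})

test_that("fit_csp solves the 2x2 generalized eigenproblem exactly", {
  m <- fit_csp(diag(c(4, 1)), diag(c(1, 4)), loading = 0)
  expect_equal(sort(m$eig1), c(0.2, 0.8))
  expect_equal(m$eig1 + m$eig2, c(1, 1), tolerance = 1e-12)
  # axis-aligned filters normalized so w' (S1+S2) w = 1
  expect_equal(abs(m$filters), diag(c(1, 1)) / sqrt(5), tolerance = 1e-10)
  expect_equal(diag(t(m$filters) %*% diag(c(5, 5)) %*% m$filters), c(1, 1),
               tolerance = 1e-10)
  # indistinguishable classes: all eigenvalue pairs 1/2
  m2 <- fit_csp(diag(2) / 2, diag(2) / 2, loading = 0)
  expect_equal(m2$eig1, c(0.5, 0.5), tolerance = 1e-12)
})

test_that("fit_csp simultaneously diagonalizes random SPD pairs", {
  for (s in 1:5) {
    n <- 4
    s1 <- rand_spd(n, seed = 100 + s)
    s2 <- rand_spd(n, seed = 200 + s)
    m <- fit_csp(s1, s2)
    d1 <- t(m$filters) %*% s1 %*% m$filters
    d2 <- t(m$filters) %*% s2 %*% m$filters
    expect_lt(max(abs(d1 - diag(diag(d1)))), 1e-8)
    expect_lt(max(abs(d2 - diag(diag(d2)))), 1e-8)
    expect_equal(diag(d1) + diag(d2), rep(1, n), tolerance = 1e-8)
    expect_equal(m$eig1 + m$eig2, rep(1, n), tolerance = 1e-8)
    # patterns invert the filters
    expect_equal(m$patterns %*% m$filters, diag(n), tolerance = 1e-8)
  }
})

test_that("fit_csp matches a brute-force joint diagonalization oracle", {
  # oracle: whiten the composite with an eigendecomposition written out
  # longhand, then eigendecompose the whitened class-2 covariance
  oracle_csp <- function(s1, s2) {
    C <- s1 + s2
    ec <- eigen(C, symmetric = TRUE)
    Wh <- diag(1 / sqrt(ec$values)) %*% t(ec$vectors)
    ew <- eigen(Wh %*% s2 %*% t(Wh), symmetric = TRUE)
    t(Wh) %*% ew$vectors  # columns: filters, eigenvalues ew$values for class 2
  }
  for (s in 1:6) {
    n <- sample(2:4, 1)
    s1 <- rand_spd(n, seed = 300 + s)
    s2 <- rand_spd(n, seed = 400 + s)
    m <- fit_csp(s1, s2, loading = 0)
    W_o <- oracle_csp(s1, s2)
    # match columns up to sign and permutation
    for (j in seq_len(n)) {
      agree <- apply(W_o, 2, function(w) min(max(abs(w - m$filters[, j])),
                                             max(abs(w + m$filters[, j]))))
      expect_lt(min(agree), 1e-6)
    }
  }
})

test_that("component scores behave as designed", {
  # build a model with identity filters over 2 channels and controlled powers
  e <- make_var_epochs(n_per_class = 21, vars = list(c(1, 3), c(3, 1)),
                       nt = 500, seed = 33)
  m <- fit_csp(class_covariances(e))
  rom <- score_components(m, e, "rom")
  a <- score_components(m, e, "auc")
  expect_true(all(rom >= 0 & rom <= 1))
  # both components are discriminative, with opposite polarity
  expect_gt(max(rom), 0.7); expect_lt(min(rom), 0.3)
  expect_gt(max(abs(a - 0.5)), 0.4)
  # eigenvalue score is just eig2
  expect_identical(score_components(m, e, "eigenvalue"), m$eig2)
  # identical class distributions: chance scores
  e0 <- make_var_epochs(n_per_class = 20, vars = list(c(1, 1), c(1, 1)),
                        nt = 400, seed = 34)
  m0 <- fit_csp(class_covariances(e0))
  expect_lt(max(abs(score_components(m0, e0, "rom") - 0.5)), 0.15)
  expect_lt(max(abs(score_components(m0, e0, "auc") - 0.5)), 0.2)
})

test_that("ratio of medians resists an outlier trial that moves the eigenvalues", {
  e <- make_var_epochs(n_per_class = 15, vars = list(c(4, 1), c(1, 4)),
                       nt = 400, seed = 35)
  m <- fit_csp(class_covariances(e))
  rom0 <- score_components(m, e, "rom")
  e2 <- e
  # one outlier trial with a rogue spatial structure
  e2$data[1, 1, ] <- e2$data[1, 1, ] + 6 * e2$data[1, 2, ]
  m2 <- fit_csp(class_covariances(e2))
  rom2 <- score_components(m2, e2, "rom")
  expect_gt(max(abs(m2$eig2 - m$eig2)), 1e-4)       # eigenvalues shift
  expect_lt(max(abs(sort(rom2) - sort(rom0))), 0.06) # medians barely move
})

test_that("feature extraction returns six log-variance columns and known values", {
  e <- make_var_epochs(n_per_class = 12, vars = list(rep(c(4, 1), 5), rep(c(1, 4), 5)),
                       nt = 300, seed = 36)
  m <- fit_csp(class_covariances(e))
  feats <- select_and_extract(m, e, n_per_class = 3)
  expect_equal(ncol(feats), 6)
  expect_equal(nrow(feats), 24)
  model <- attr(feats, "model")
  expect_length(model$selected, 6)
  expect_lte(length(select_and_extract(m, e, "heuristic")[1, ]), 6)

  # pure sinusoid of amplitude a through a unit filter: log-variance = log(a^2/2)
  fs <- 100; nt <- 1000
  tt <- seq_len(nt) / fs
  a <- 3
  data <- array(0, c(2, 1, nt))
  data[1, 1, ] <- a * sin(2 * pi * 7 * tt)
  data[2, 1, ] <- a * sin(2 * pi * 7 * tt + 1)
  ep <- smrbci:::new_epochs(data, tt, c("A", "B"), fs, "ch1")
  unit <- structure(list(filters = matrix(1, 1, 1, dimnames = list("ch1", NULL)),
                         patterns = matrix(1, 1, 1), eig1 = 0.5, eig2 = 0.5,
                         scores = NULL, selected = 1, classes = c("A", "B")),
                    class = "csp")
  bp <- smrbci:::csp_band_power(unit, ep, 1)
  expect_equal(log(bp[1, 1]), log(a^2 / 2), tolerance = 0.01)
})

test_that("scaling the data shifts log-variance features additively only", {
  e <- make_var_epochs(n_per_class = 10, vars = list(c(4, 1), c(1, 4)),
                       nt = 300, seed = 37)
  m <- fit_csp(class_covariances(e))
  f1 <- select_and_extract(m, e, 3)
  e2 <- e; e2$data <- e$data * 5
  m2 <- fit_csp(class_covariances(e2))
  f2 <- select_and_extract(m2, e2, 3)
  shift <- f2 - f1
  expect_lt(max(abs(shift - 2 * log(5))), 1e-8)
  expect_equal(score_components(m2, e2, "rom"), score_components(m, e, "rom"),
               tolerance = 1e-8)
})

test_that("CSP models serialize to JSON and back", {
  e <- make_var_epochs(n_per_class = 8, vars = list(c(4, 1), c(1, 4)),
                       nt = 200, seed = 38)
  m <- fit_csp(class_covariances(e))
  m$band_interval <- band_interval(8, 12, 500, 3500)
  path <- tempfile(fileext = ".json")
  write_csp(m, path)
  back <- read_csp(path)
  expect_equal(back$filters, m$filters, tolerance = 1e-12)
  expect_equal(back$eig2, m$eig2, tolerance = 1e-12)
  expect_equal(back$band_interval$f_lo, 8)
  unlink(path)
})
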