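# Nine-parameter model of the EEG rest spectrum: 1/f-type noise floor plus
# Gaussian mu and beta peaks, fitted in the dB domain over 2-35 Hz; yields the
# per-channel SMR-strength and the two-channel SMR predictor.

psd_model_eval <- function(par, f) {
  par[["k_n1"]] + par[["k_n2"]] * f^(-par[["lambda"]]) +
    par[["k_alpha"]] * exp(-(f - par[["mu_alpha"]])^2 / (2 * par[["sigma_alpha"]]^2)) +
    par[["k_beta"]] * exp(-(f - par[["mu_beta"]])^2 / (2 * par[["sigma_beta"]]^2))
}

psd_noise_eval <- function(par, f) {
  par[["k_n1"]] + par[["k_n2"]] * f^(-par[["lambda"]])
}

psd_par_names <- c("lambda", "k_n1", "k_n2", "k_alpha", "mu_alpha", "sigma_alpha",
                   "k_beta", "mu_beta", "sigma_beta")

psd_lower <- c(lambda = 0, k_n1 = -60, k_n2 = 0, k_alpha = 0, mu_alpha = 7,
               sigma_alpha = 0.5, k_beta = 0, mu_beta = 15, sigma_beta = 0.5)
psd_upper <- c(lambda = 4, k_n1 = 60, k_n2 = 200, k_alpha = 40, mu_alpha = 14,
               sigma_alpha = 6, k_beta = 40, mu_beta = 30, sigma_beta = 6)

psd_rss <- function(par, f, y) {
  names(par) <- psd_par_names
  sum((y - psd_model_eval(par, f))^2)
}

# analytic gradient of psd_rss
psd_rss_grad <- function(par, f, y) {
  names(par) <- psd_par_names
  r <- psd_model_eval(par, f) - y  # residual
  fa <- f^(-par[["lambda"]])
  ga <- exp(-(f - par[["mu_alpha"]])^2 / (2 * par[["sigma_alpha"]]^2))
  gb <- exp(-(f - par[["mu_beta"]])^2 / (2 * par[["sigma_beta"]]^2))
  da <- f - par[["mu_alpha"]]; db <- f - par[["mu_beta"]]
  g <- c(
    lambda = sum(r * (-par[["k_n2"]] * fa * log(f))),
    k_n1 = sum(r),
    k_n2 = sum(r * fa),
    k_alpha = sum(r * ga),
    mu_alpha = sum(r * par[["k_alpha"]] * ga * da / par[["sigma_alpha"]]^2),
    sigma_alpha = sum(r * par[["k_alpha"]] * ga * da^2 / par[["sigma_alpha"]]^3),
    k_beta = sum(r * gb),
    mu_beta = sum(r * par[["k_beta"]] * gb * db / par[["sigma_beta"]]^2),
    sigma_beta = sum(r * par[["k_beta"]] * gb * db^2 / par[["sigma_beta"]]^3)
  )
  2 * g
}

# noise-only (3-parameter) fit, used for starts and for the residual bound
fit_noise_floor <- function(f, y) {
  best <- NULL
  for (lam0 in c(0.5, 1, 1.5, 2.5)) {
    st <- c(lambda = lam0, k_n1 = min(y), k_n2 = max(stats::median(y) - min(y), 1))
    o <- try(stats::optim(st, function(p) {
      sum((y - (p[2] + p[3] * f^(-p[1])))^2)
    }, method = "L-BFGS-B",
    lower = c(0, -60, 0), upper = c(4, 60, 200),
    control = list(maxit = 500)), silent = TRUE)
    if (inherits(o, "try-error")) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) stopf("noise-floor fit failed")
  names(best$par) <- c("lambda", "k_n1", "k_n2")
  best
}

#' Fit the nine-parameter rest-spectrum model
#'
#' Models the dB power spectrum over 2-35 Hz as `n(f) + g_a(f) + g_b(f)` with
#' a hyperbolic noise floor `n(f) = k_n1 + k_n2 * f^-lambda` and unnormalized
#' Gaussian peaks in the mu band (7-14 Hz) and beta band (15-30 Hz). The nine
#' parameters minimize the L2 norm of the difference to the observed spectrum
#' on the frequency grid, by bounded nonlinear least squares with multiple
#' starts: peak locations are seeded at the largest local maxima of the
#' spectrum minus the noise-floor fit, plus default mu/beta positions. The
#' residual is guaranteed not to exceed the noise-only sub-model's residual
#' (peaks can only help).
#'
#' @param psd A `spectral_estimate` (see [welch_psd()]), or a list with
#'   `values` (dB) and `freqs`.
#' @param channel Channel name (row of `psd$values`); default first row.
#' @param freq_range Fit range in Hz (default 2-35).
#' @return An object of class `psd_fit`: `par` (named 9-vector), `residual`
#'   (L2 norm of the fit error), `smr_strength` (dB), `channel`, `freqs`,
#'   `observed`, `fitted`, `noise`.
#' @export
fit_psd_model <- function(psd, channel = NULL, freq_range = c(2, 35)) {
  if (is.null(channel)) channel <- rownames(psd$values)[1]
  sel <- which(psd$freqs >= freq_range[1] - 1e-9 & psd$freqs <= freq_range[2] + 1e-9)
  f <- psd$freqs[sel]
  y <- psd$values[channel, sel]
  if (length(f) < 12) stopf("spectrum must cover %g-%g Hz", freq_range[1], freq_range[2])

  nf <- fit_noise_floor(f, y)
  resid_noise <- sqrt(nf$value)
  excess <- y - (nf$par[["k_n1"]] + nf$par[["k_n2"]] * f^(-nf$par[["lambda"]]))

  # candidate peak seeds from local maxima of the excess, split by band
  seed_mu <- f[f >= 7 & f <= 14][which.max(excess[f >= 7 & f <= 14])]
  seed_beta <- f[f >= 15 & f <= 30][which.max(excess[f >= 15 & f <= 30])]
  amp_mu <- max(excess[f >= 7 & f <= 14], 0.1)
  amp_beta <- max(excess[f >= 15 & f <= 30], 0.1)
  starts <- list(
    c(nf$par, k_alpha = amp_mu, mu_alpha = seed_mu, sigma_alpha = 1.5,
      k_beta = amp_beta, mu_beta = seed_beta, sigma_beta = 2.5),
    c(nf$par, k_alpha = amp_mu, mu_alpha = 10, sigma_alpha = 1,
      k_beta = amp_beta, mu_beta = 20, sigma_beta = 2),
    c(nf$par, k_alpha = amp_mu / 2, mu_alpha = seed_mu, sigma_alpha = 3,
      k_beta = amp_beta / 2, mu_beta = seed_beta, sigma_beta = 4),
    c(nf$par, k_alpha = 0.1, mu_alpha = 12, sigma_alpha = 2,
      k_beta = 0.1, mu_beta = 25, sigma_beta = 3),
    c(lambda = 1, k_n1 = min(y), k_n2 = 20, k_alpha = amp_mu,
      mu_alpha = seed_mu, sigma_alpha = 1.5, k_beta = amp_beta,
      mu_beta = seed_beta, sigma_beta = 2.5)
  )
  starts <- lapply(starts, function(s) {
    s <- s[psd_par_names]
    pmin(pmax(s, psd_lower + 1e-9), psd_upper - 1e-9)
  })

  best <- NULL
  for (st in starts) {
    o <- try(stats::optim(st, function(p) psd_rss(p, f, y), method = "L-BFGS-B",
                          lower = psd_lower, upper = psd_upper,
                          control = list(maxit = 1000, factr = 1e4)),
             silent = TRUE)
    if (inherits(o, "try-error")) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) stopf("rest-spectrum fit did not converge from any start")
  # polish the winning start to high precision
  pol <- try(stats::optim(best$par, function(p) psd_rss(p, f, y),
                          gr = function(p) psd_rss_grad(p, f, y),
                          method = "L-BFGS-B", lower = psd_lower, upper = psd_upper,
                          control = list(maxit = 5000, factr = 1, pgtol = 0)),
             silent = TRUE)
  if (!inherits(pol, "try-error") && pol$value <= best$value) best <- pol
  par <- best$par
  names(par) <- psd_par_names
  residual <- sqrt(best$value)
  if (residual > resid_noise + 1e-9) {
    # peaks can only help: fall back to the noise floor with zero peaks
    par <- c(nf$par, k_alpha = 0, mu_alpha = 10, sigma_alpha = 1.5,
             k_beta = 0, mu_beta = 20, sigma_beta = 2.5)[psd_par_names]
    residual <- resid_noise
  }
  fitted <- psd_model_eval(par, f)
  noise <- psd_noise_eval(par, f)
  structure(list(par = par, residual = residual,
                 smr_strength = max(fitted - noise),
                 channel = channel, freqs = f, observed = y,
                 fitted = fitted, noise = noise,
                 noise_residual = resid_noise),
            class = "psd_fit")
}

#' @export
print.psd_fit <- function(x, ...) {
  cat(sprintf("<psd_fit> channel %s: SMR-strength %.2f dB, residual %.3f\n",
              x$channel, x$smr_strength, x$residual))
  cat(sprintf("  noise: lambda %.2f, k_n1 %.2f, k_n2 %.2f\n",
              x$par[["lambda"]], x$par[["k_n1"]], x$par[["k_n2"]]))
  cat(sprintf("  mu peak: %.2f dB @ %.1f Hz (sd %.1f); beta peak: %.2f dB @ %.1f Hz (sd %.1f)\n",
              x$par[["k_alpha"]], x$par[["mu_alpha"]], x$par[["sigma_alpha"]],
              x$par[["k_beta"]], x$par[["mu_beta"]], x$par[["sigma_beta"]]))
  invisible(x)
}

#' @export
coef.psd_fit <- function(object, ...) object$par

#' @export
fitted.psd_fit <- function(object, ...) object$fitted

#' @export
residuals.psd_fit <- function(object, ...) object$observed - object$fitted

#' @export
plot.psd_fit <- function(x, ...) {
  graphics::plot(x$freqs, x$observed, type = "l", xlab = "frequency [Hz]",
                 ylab = "PSD [dB]", main = sprintf("rest spectrum, %s", x$channel), ...)
  graphics::lines(x$freqs, x$fitted, lty = 3, col = "blue")
  graphics::lines(x$freqs, x$noise, lty = 2, col = "red")
  graphics::legend("topright", c("PSD", "model", "noise"), lty = c(1, 3, 2),
                   col = c("black", "blue", "red"), bty = "n")
  invisible(x)
}

#' SMR-strength of a fitted rest spectrum
#'
#' The maximal distance (dB) between the fitted spectrum model and its fitted
#' noise floor over the evaluation grid: the prominence of the mu/beta peaks
#' above the 1/f background at that channel.
#'
#' @param fit A `psd_fit`.
#' @return Strength in dB (>= 0).
#' @export
smr_strength <- function(fit) {
  stopifnot(inherits(fit, "psd_fit"))
  max(fit$fitted - fit$noise)
}

#' Rest-spectrum SMR predictor
#'
#' Laplacian-derives C3 and C4 from an eyes-open rest recording, estimates
#' their Welch spectra (dB, 0.5 Hz resolution), fits the nine-parameter
#' spectrum model to each, and returns the mean of the two SMR-strengths.
#'
#' @param rest An `eeg_recording` at rest.
#' @param montage A `bci_montage` containing C3 and C4 with neighbors.
#' @param channels The two channels averaged (default C3, C4).
#' @return List with `value` (the predictor, dB) and `fits` (named list of
#'   `psd_fit` objects).
#' @export
compute_predictor <- function(rest, montage = rest$montage,
                              channels = c("C3", "C4")) {
  if (!all(channels %in% montage$channels)) {
    stopf("montage lacks predictor channel(s): %s",
          paste(setdiff(channels, montage$channels), collapse = ", "))
  }
  lap <- laplacian(rest, montage, channels)
  psd <- welch_psd(lap, channels, freq_range = c(2, 35))
  fits <- lapply(channels, function(ch) fit_psd_model(psd, ch))
  names(fits) <- channels
  list(value = mean(vapply(fits, smr_strength, 0)), fits = fits)
}

#' Expected-control flag from the SMR predictor
#'
#' Users with an SMR predictor at or above the threshold (default 3 dB) are
#' expected to reach BCI control; the boundary value counts as
#' expected-control.
#'
#' @param predictor_value Predictor value in dB.
#' @param threshold Threshold in dB (default 3).
#' @return Logical flag.
#' @export
predict_control <- function(predictor_value, threshold = 3) {
  predictor_value >= threshold
}
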