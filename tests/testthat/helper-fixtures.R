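# Shared fixtures built in code.

fix_montage <- make_montage("motor27")

# epochs with prescribed per-class channel variances: trials x channels x time
# Gaussian noise, channel ch of class k scaled by sqrt(vars[[k]][ch])
make_var_epochs <- function(n_per_class = 20, vars = list(c(4, 1), c(1, 4)),
                            nt = 200, fs = 100, seed = 1,
                            classes = c("A", "B")) {
  nch <- length(vars[[1]])
  withr_seed <- function(expr) smrbci:::with_local_seed(seed, expr)
  withr_seed({
    labels <- rep(classes, each = n_per_class)
    data <- array(0, c(2 * n_per_class, nch, nt))
    for (i in seq_along(labels)) {
      v <- vars[[match(labels[i], classes)]]
      data[i, , ] <- matrix(rnorm(nch * nt), nch, nt) * sqrt(v)
    }
    smrbci:::new_epochs(data, seq(0, by = 1 / fs, length.out = nt), labels, fs,
                        paste0("ch", seq_len(nch)))
  })
}

# quick small task run for selection / classification tests
quick_run <- function(template = "I", seed = 1, n_per_class = 10,
                      classes = c("Left", "Right"), run_type = "MI-Cb",
                      profile = NULL) {
  if (is.null(profile)) profile <- make_user_profile(template, seed = seed)
  simulate_run(profile,
               run_spec(run_type, n_per_class, classes = classes,
                        block_size = length(classes)),
               fix_montage, seed = seed + 1000L)
}

# random symmetric positive definite matrix
rand_spd <- function(n, seed = 1) {
  smrbci:::with_local_seed(seed, {
    A <- matrix(rnorm(n * n), n, n)
    crossprod(A) / n + diag(0.1, n)
  })
}

# spectral_estimate from an explicit dB curve on the 2-35 Hz grid
psd_from_curve <- function(y, f = seq(2, 35, by = 0.5), channel = "C3") {
  structure(list(values = matrix(y, 1, dimnames = list(channel, NULL)),
                 freqs = f, resolution = f[2] - f[1]),
            class = "spectral_estimate")
}
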