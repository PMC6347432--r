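# Common Spatial Patterns by simultaneous diagonalization of class covariances.

#' Class covariance matrices
#'
#' One spatial covariance per trial (over the time samples), normalized by its
#' trace so that trial-power outliers do not dominate, then averaged within
#' each class.
#'
#' @param epochs Band-pass filtered `eeg_epochs` with two classes, ideally
#'   segmented to the discriminative interval.
#' @param classes Optional length-2 class order.
#' @return List with `sigma1`, `sigma2` (channels x channels) and `classes`.
#' @export
class_covariances <- function(epochs, classes = NULL) {
  if (is.null(classes)) classes <- sort(unique(as.character(epochs$labels)))
  stopifnot(length(classes) == 2)
  d <- dim(epochs$data)
  tc <- trial_covs(epochs)
  covs <- function(cls) {
    idx <- which(epochs$labels == cls)
    if (length(idx) < 2) stopf("need >= 2 trials per class (class %s has %d)",
                               cls, length(idx))
    avg_trial_cov(tc, idx, epochs$channels)
  }
  s1 <- covs(classes[1]); s2 <- covs(classes[2])
  if (qr(s1 + s2)$rank < d[2]) {
    warnf("pooled covariance is rank deficient; diagonal loading will regularize")
  }
  list(sigma1 = s1, sigma2 = s2, classes = classes)
}

# per-trial spatial covariances, each normalized by its trace:
# matrix (nch*nch) x trials
trial_covs <- function(epochs) {
  d <- dim(epochs$data)
  out <- matrix(0, d[2] * d[2], d[1])
  for (tr in seq_len(d[1])) {
    X <- matrix(epochs$data[tr, , ], d[2], d[3])
    X <- X - rowMeans(X)
    C <- tcrossprod(X) / d[3]
    out[, tr] <- C / sum(diag(C))
  }
  out
}

avg_trial_cov <- function(tc, idx, channels) {
  nch <- as.integer(sqrt(nrow(tc)))
  S <- matrix(rowMeans(tc[, idx, drop = FALSE]), nch, nch)
  S <- (S + t(S)) / 2
  dimnames(S) <- list(channels, channels)
  S
}

#' Fit Common Spatial Patterns
#'
#' Solves the generalized eigenproblem `Sigma2 W = (Sigma1 + Sigma2) W Lambda`
#' by whitening the composite covariance, so that `W' Sigma1 W` and
#' `W' Sigma2 W` are simultaneously diagonal with `Lambda1 + Lambda2 = I`.
#' Filters with extreme eigenvalues maximize the variance ratio between the
#' two classes. Components are sorted by `max(eig1, eig2)` descending; each
#' filter is scaled so that the largest-magnitude entry of its spatial pattern
#' is positive.
#'
#' @param sigma1,sigma2 Class covariance matrices (see [class_covariances()]),
#'   or a list as returned by it passed as `sigma1`.
#' @param loading Diagonal loading factor relative to the trace (default 1e-9)
#'   applied to the composite before whitening.
#' @param classes Optional class labels carried into the model.
#' @return An object of class `csp`: `filters` (channels x components),
#'   `patterns` (components x channels), `eig1`, `eig2`, `scores` (NULL until
#'   [score_components()]), `selected`, `classes`.
#' @export
fit_csp <- function(sigma1, sigma2 = NULL, loading = 1e-9, classes = NULL) {
  if (is.list(sigma1) && is.null(sigma2)) {
    classes <- sigma1$classes
    sigma2 <- sigma1$sigma2
    sigma1 <- sigma1$sigma1
  }
  n <- nrow(sigma1)
  comp <- sigma1 + sigma2
  comp <- comp + diag(loading * sum(diag(comp)), n)
  ec <- eigen(comp, symmetric = TRUE)
  if (min(ec$values) <= 0) {
    stopf("composite covariance not positive definite (min eigenvalue %.3e)",
          min(ec$values))
  }
  P <- ec$vectors %*% diag(1 / sqrt(ec$values), n) %*% t(ec$vectors)  # whitener
  S <- P %*% sigma2 %*% P
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  W <- P %*% es$vectors
  eig2 <- es$values
  eig1 <- 1 - eig2
  ord <- order(pmax(eig1, eig2), decreasing = TRUE)
  W <- W[, ord, drop = FALSE]
  eig1 <- eig1[ord]; eig2 <- eig2[ord]
  A <- solve(W)  # rows = spatial patterns
  for (j in seq_len(n)) {
    s <- sign(A[j, which.max(abs(A[j, ]))])
    if (s < 0) { W[, j] <- -W[, j]; A[j, ] <- -A[j, ] }
  }
  rownames(W) <- rownames(sigma1); colnames(A) <- rownames(sigma1)
  structure(list(filters = W, patterns = A, eig1 = eig1, eig2 = eig2,
                 scores = NULL, selected = NULL, classes = classes,
                 band_interval = NULL), class = "csp")
}

#' @export
print.csp <- function(x, ...) {
  cat(sprintf("<csp> %d channels, %d components; classes: %s\n",
              nrow(x$filters), ncol(x$filters),
              if (is.null(x$classes)) "?" else paste(x$classes, collapse = " vs ")))
  cat("  eigenvalue pairs (class 2):",
      paste(sprintf("%.2f", utils::head(x$eig2, 6)), collapse = " "), "...\n")
  if (!is.null(x$selected)) {
    cat("  selected components:", paste(x$selected, collapse = ", "), "\n")
  }
  invisible(x)
}

# per-trial variance of CSP-projected signals: trials x components.
# Channels are matched by name when the model was fitted on a channel subset.
csp_band_power <- function(model, epochs, components = NULL) {
  W <- model$filters
  if (!is.null(components)) W <- W[, components, drop = FALSE]
  d <- dim(epochs$data)
  if (!is.null(rownames(model$filters)) &&
      !identical(rownames(model$filters), epochs$channels)) {
    ci <- match(rownames(model$filters), epochs$channels)
    if (anyNA(ci)) stopf("epochs lack CSP model channel(s)")
  } else {
    ci <- seq_len(d[2])
  }
  M <- matrix(aperm(epochs$data[, ci, , drop = FALSE], c(2, 3, 1)),
              length(ci), d[3] * d[1])
  P <- crossprod(W, M)                       # components x (time, trial)
  A <- array(P, c(ncol(W), d[3], d[1]))
  s1 <- colSums(aperm(A, c(2, 1, 3)))        # components x trials
  s2 <- colSums(aperm(A^2, c(2, 1, 3)))
  t((s2 - s1^2 / d[3]) / (d[3] - 1))
}

#' Score CSP components for selection
#'
#' `"eigenvalue"` returns the class-2 eigenvalues; `"rom"` the
#' ratio-of-medians `m2 / (m1 + m2)` of per-trial component band power, robust
#' against trial outliers (scores near 0 or 1 mark discriminative
#' components); `"auc"` the area under the ROC curve of log band power;
#' `"fisher"` the Fisher discriminant ratio.
#'
#' @param model A `csp` object.
#' @param epochs The epochs the model was fitted on (band-filtered,
#'   segmented).
#' @param method Scoring method.
#' @return Numeric score per component (also stored when assigned back).
#' @export
score_components <- function(model, epochs,
                             method = c("rom", "eigenvalue", "auc", "fisher")) {
  method <- match.arg(method)
  if (method == "eigenvalue") return(model$eig2)
  classes <- if (!is.null(model$classes)) model$classes
             else sort(unique(as.character(epochs$labels)))
  bp <- csp_band_power(model, epochs)
  i1 <- epochs$labels == classes[1]; i2 <- epochs$labels == classes[2]
  if (method == "rom") {
    m1 <- apply(bp[i1, , drop = FALSE], 2, stats::median)
    m2 <- apply(bp[i2, , drop = FALSE], 2, stats::median)
    if (any(m1 + m2 <= 0)) stopf("zero median band power: score undefined")
    return(m2 / (m1 + m2))
  }
  if (method == "auc") {
    return(apply(log(bp), 2, function(s) auc(s, epochs$labels, classes = classes)))
  }
  # fisher
  f <- log(bp)
  mu1 <- colMeans(f[i1, , drop = FALSE]); mu2 <- colMeans(f[i2, , drop = FALSE])
  v1 <- apply(f[i1, , drop = FALSE], 2, stats::var)
  v2 <- apply(f[i2, , drop = FALSE], 2, stats::var)
  (mu1 - mu2)^2 / (v1 + v2)
}

#' Select CSP components and extract log-variance features
#'
#' Features are the log of the per-trial variance of the CSP-filtered signals
#' (log band power). `n_per_class` = 3 reproduces the fixed six-filter choice
#' (three per class from the two ends of the eigenvalue spectrum);
#' `"heuristic"` keeps components whose ratio-of-medians score departs from
#' 0.5 by at least `rom_cut`, at most three per class and never more than six
#' in total, falling back to the best one per class when none passes.
#'
#' @param model A `csp` object.
#' @param epochs Band-filtered, segmented `eeg_epochs`.
#' @param n_per_class Integer (default 3) or `"heuristic"`.
#' @param rom_cut Heuristic cut on `|rom - 0.5|` (default 0.1).
#' @return Feature matrix (trials x selected components) with attribute
#'   `model` carrying the updated `csp` (scores and selection filled in).
#' @export
select_and_extract <- function(model, epochs, n_per_class = 3, rom_cut = 0.1) {
  bp <- csp_band_power(model, epochs)
  classes <- if (!is.null(model$classes)) model$classes
             else sort(unique(as.character(epochs$labels)))
  sel <- select_components_core(model, bp, epochs$labels, classes,
                                n_per_class, rom_cut)
  feats <- log(bp[, sel$selected, drop = FALSE])
  model$scores <- sel$rom
  model$selected <- sel$selected
  attr(feats, "model") <- model
  feats
}

# component selection from precomputed per-trial band power
select_components_core <- function(model, bp, labels, classes, n_per_class = 3,
                                   rom_cut = 0.1) {
  ncomp <- ncol(model$filters)
  i1 <- labels == classes[1]; i2 <- labels == classes[2]
  m1 <- apply(bp[i1, , drop = FALSE], 2, stats::median)
  m2 <- apply(bp[i2, , drop = FALSE], 2, stats::median)
  if (any(m1 + m2 <= 0)) stopf("zero median band power: score undefined")
  rom <- m2 / (m1 + m2)
  # order components by which class's variance they maximize
  ord1 <- order(model$eig1, decreasing = TRUE)  # class-1-dominant first
  ord2 <- order(model$eig2, decreasing = TRUE)
  if (identical(n_per_class, "heuristic")) {
    dev <- abs(rom - 0.5)
    side1 <- ord1[rom[ord1] < 0.5 & dev[ord1] >= rom_cut]
    side2 <- ord2[rom[ord2] > 0.5 & dev[ord2] >= rom_cut]
    side1 <- utils::head(side1, 3); side2 <- utils::head(side2, 3)
    if (!length(side1)) side1 <- ord1[which.max(dev[ord1])][1]
    if (!length(side2)) side2 <- ord2[which.max(dev[ord2])][1]
    if (!length(c(side1, side2))) {
      warnf("no component passed the heuristic cut; keeping best one per class")
    }
    sel <- unique(c(side1, side2))
  } else {
    k <- min(as.integer(n_per_class), floor(ncomp / 2))
    sel <- unique(c(utils::head(ord1, k), utils::head(ord2, k)))
  }
  sel <- utils::head(sel, 6)
  list(selected = sel, rom = rom)
}

#' Serialize / restore a CSP model as JSON
#'
#' @param model A `csp` object.
#' @param path File path.
#' @return `read_csp` returns the `csp` object.
#' @export
write_csp <- function(model, path) {
  obj <- list(filters = model$filters, patterns = model$patterns,
              eig1 = model$eig1, eig2 = model$eig2, scores = model$scores,
              selected = model$selected, classes = model$classes,
              channels = rownames(model$filters),
              band_interval = if (is.null(model$band_interval)) NULL
                              else unclass(model$band_interval))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_csp
#' @export
read_csp <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  filters <- as.matrix(obj$filters); rownames(filters) <- obj$channels
  patterns <- as.matrix(obj$patterns); colnames(patterns) <- obj$channels
  bi <- obj$band_interval
  structure(list(filters = filters, patterns = patterns, eig1 = obj$eig1,
                 eig2 = obj$eig2, scores = obj$scores, selected = obj$selected,
                 classes = obj$classes,
                 band_interval = if (is.null(bi)) NULL else
                   band_interval(bi$f_lo, bi$f_hi, bi$t_start, bi$t_end,
                                 isTRUE(bi$low_confidence))),
            class = "csp")
}
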