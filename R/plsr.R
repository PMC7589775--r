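# NIPALS PLS1 core on a centered problem; returns per-factor bases and the
# accumulated regression vectors so cross-validation can reuse one
# decomposition for every factor count.
pls1_nipals <- function(Xc, yc, ncomp, tol = 1e-12) {
  n <- nrow(Xc); J <- ncol(Xc)
  W <- matrix(0, J, ncomp); P <- matrix(0, J, ncomp); q <- numeric(ncomp)
  X <- Xc; y <- yc
  actual <- 0L
  for (a in seq_len(ncomp)) {
    w <- crossprod(X, y)
    nw <- sqrt(sum(w^2))
    if (nw < tol * max(1, sqrt(sum(Xc^2)))) break  # rank exhausted
    w <- w / nw
    t <- X %*% w
    tt <- sum(t^2)
    if (tt < tol) break
    p <- crossprod(X, t) / tt
    qa <- sum(y * t) / tt
    X <- X - t %*% t(p)
    y <- y - qa * t
    W[, a] <- w; P[, a] <- p; q[a] <- qa
    actual <- a
  }
  list(W = W[, seq_len(actual), drop = FALSE],
       P = P[, seq_len(actual), drop = FALSE],
       q = q[seq_len(actual)], ncomp = actual)
}

# beta vector using the first a factors of a NIPALS decomposition
pls1_beta <- function(dec, a) {
  W <- dec$W[, seq_len(a), drop = FALSE]
  P <- dec$P[, seq_len(a), drop = FALSE]
  drop(W %*% solve(t(P) %*% W, dec$q[seq_len(a)]))
}

#' Fit a PLS1 regression of concentration on spectra
#'
#' Sequential NIPALS extraction of `ncomp` latent factors on the centered
#' data (centering only, no band scaling -- the spectroscopy convention).
#' The latent decomposition is collapsed to a single affine map
#' `y = intercept + x . beta`.
#'
#' @param X `spectral_set` or matrix of predictor spectra.
#' @param y response vector (adulterant concentration, %); if missing and `X`
#'   is a `spectral_set`, `meta$concentration_pct` is used.
#' @param ncomp number of latent factors `A >= 1`.
#' @param preprocess optional [preprocess_spec()]; fitted on `X` and applied
#'   before fitting (and to spectra at prediction time).
#' @return Object of class `plsr1` with `beta`, `intercept`, the latent
#'   basis, the chosen `ncomp` and calibration fit statistics (`r2_cal`,
#'   `sec`).
#' @export
pls1_fit <- function(X, y = NULL, ncomp = 2L, preprocess = NULL) {
  if (!is.null(preprocess)) {
    preprocess <- fit_preprocess(preprocess, X)
    X <- apply_preprocess(preprocess, X)
  }
  wl <- NULL
  if (inherits(X, "spectral_set")) {
    if (is.null(y)) y <- X$meta$concentration_pct
    wl <- X$wavelengths
    X <- X$spectra
  } else X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (length(y) != n) stop("length(y) must match nrow(X)")
  if (stats::var(y) == 0) stop("y is constant: nothing to regress")
  ncomp <- as.integer(ncomp)
  if (ncomp < 1L || ncomp >= min(n, ncol(X) + 1L)) {
    stop("need 1 <= ncomp < min(n, bands + 1)")
  }
  x_center <- colMeans(X); y_center <- mean(y)
  dec <- pls1_nipals(sweep(X, 2, x_center), y - y_center, ncomp)
  if (dec$ncomp < ncomp) {
    stop(sprintf("rank deficiency: only %d factor(s) extractable", dec$ncomp))
  }
  beta <- pls1_beta(dec, ncomp)
  intercept <- y_center - sum(x_center * beta)
  fitted <- intercept + drop(X %*% beta)
  rep_cal <- evaluate_regression(y, fitted)
  structure(
    list(x_center = x_center, y_center = y_center,
         weights = dec$W, x_loadings = dec$P, y_loadings = dec$q,
         beta = beta, intercept = intercept, ncomp = ncomp,
         preprocess = preprocess, wavelengths = wl,
         fit_stats = list(r2_cal = rep_cal$r2, sec = rep_cal$se)),
    class = "plsr1")
}

#' @export
print.plsr1 <- function(x, ...) {
  cat(sprintf("<plsr1> A=%d, %d bands, R2cal=%.4f, SEC=%.3f%%\n",
              x$ncomp, length(x$beta), x$fit_stats$r2_cal, x$fit_stats$sec))
  invisible(x)
}

#' Predict concentrations from spectra
#'
#' @param object a `plsr1` model.
#' @param X `spectral_set` or matrix.
#' @param ... unused.
#' @return Numeric vector of predicted concentrations (unclipped).
#' @export
predict.plsr1 <- function(object, X, ...) {
  if (!is.null(object$preprocess)) X <- apply_preprocess(object$preprocess, X)
  if (inherits(X, "spectral_set")) X <- X$spectra
  X <- as.matrix(X)
  if (ncol(X) != length(object$beta)) {
    stop("band count does not match the fitted model")
  }
  object$intercept + drop(X %*% object$beta)
}

#' Leave-one-out factor selection
#'
#' For each factor count `A = 1..A_max`, every sample is predicted from a
#' model fitted on the remaining `n - 1`; RMSECV is the root mean squared
#' leave-one-out error. The selected `A` minimizes RMSECV, ties broken
#' toward fewer factors.
#'
#' @param X `spectral_set` or matrix (already preprocessed, or pass
#'   `preprocess` to transform once before the folds).
#' @param y response vector (defaults to `meta$concentration_pct`).
#' @param A_max largest factor count to evaluate.
#' @param preprocess optional [preprocess_spec()] fitted on the full set and
#'   applied before cross-validating.
#' @return List with `rmsecv` (one value per `A`) and `A_selected`.
#' @export
pls1_loo <- function(X, y = NULL, A_max = 10L, preprocess = NULL) {
  if (!is.null(preprocess)) {
    preprocess <- fit_preprocess(preprocess, X)
    X <- apply_preprocess(preprocess, X)
  }
  if (inherits(X, "spectral_set")) {
    if (is.null(y)) y <- X$meta$concentration_pct
    X <- X$spectra
  } else X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 samples for leave-one-out")
  A_max <- min(as.integer(A_max), n - 2L, ncol(X))
  pred <- matrix(NA_real_, n, A_max)
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]; yi <- y[-i]
    xc <- colMeans(Xi); yc <- mean(yi)
    dec <- pls1_nipals(sweep(Xi, 2, xc), yi - yc, A_max)
    for (a in seq_len(dec$ncomp)) {
      beta <- pls1_beta(dec, a)
      pred[i, a] <- yc + sum((X[i, ] - xc) * beta)
    }
  }
  rmsecv <- sqrt(colMeans((pred - y)^2))
  list(rmsecv = rmsecv, A_selected = which.min(rmsecv))
}

#' Regression error report
#'
#' `se` is the root-mean-square residual (the SEC/SEP statistic); `r2` is
#' `1 - SSres / SStot` about the evaluated set's own mean.
#'
#' @param y_true,y_pred numeric vectors of equal length `n >= 2`.
#' @return List with `r2`, `se`, `n`, `residuals`.
#' @export
evaluate_regression <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  n <- length(y_true)
  if (n < 2L) stop("need at least 2 observations")
  res <- y_true - y_pred
  ss_res <- sum(res^2)
  ss_tot <- sum((y_true - mean(y_true))^2)
  list(r2 = 1 - ss_res / ss_tot, se = sqrt(mean(res^2)), n = n,
       residuals = res)
}

#' Save / load a PLS1 model as YAML
#'
#' @param model a `plsr1` model.
#' @param path output path (conventionally `.plsr`).
#' @return `path` invisibly; `load_plsr()` returns the model.
#' @export
save_plsr <- function(model, path) {
  stopifnot(inherits(model, "plsr1"))
  lst <- list(
    type = "plsr1",
    x_center = as.numeric(model$x_center), y_center = model$y_center,
    weights = apply(model$weights, 2, as.numeric, simplify = FALSE),
    x_loadings = apply(model$x_loadings, 2, as.numeric, simplify = FALSE),
    y_loadings = as.numeric(model$y_loadings),
    beta = as.numeric(model$beta), intercept = model$intercept,
    ncomp = model$ncomp,
    wavelengths = if (is.null(model$wavelengths)) NULL
                  else as.numeric(model$wavelengths),
    fit_stats = model$fit_stats,
    preprocess = if (is.null(model$preprocess)) NULL
                 else preprocess_to_list(model$preprocess)
  )
  yaml::write_yaml(lst, path, precision = 17L)
  invisible(path)
}

#' @rdname save_plsr
#' @export
load_plsr <- function(path) {
  lst <- yaml::read_yaml(path)
  if (is.null(lst$type) || lst$type != "plsr1") stop("not a plsr1 model file")
  structure(
    list(x_center = as.numeric(lst$x_center), y_center = lst$y_center,
         weights = do.call(cbind, lapply(lst$weights, as.numeric)),
         x_loadings = do.call(cbind, lapply(lst$x_loadings, as.numeric)),
         y_loadings = as.numeric(lst$y_loadings),
         beta = as.numeric(lst$beta), intercept = lst$intercept,
         ncomp = as.integer(lst$ncomp),
         wavelengths = if (is.null(lst$wavelengths)) NULL
                       else as.numeric(lst$wavelengths),
         fit_stats = lst$fit_stats,
         preprocess = if (is.null(lst$preprocess)) NULL
                      else preprocess_from_list(lst$preprocess)),
    class = "plsr1")
}
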