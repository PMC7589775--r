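#' Chi-square degrees of freedom by the method of moments
#'
#' A scaled chi-square with `N` degrees of freedom has `2 * mean^2 / var ==
#' N` whatever the scale, so `N` is estimated as `round(2 * mean(d)^2 /
#' var(d))`, clipped to \[1, 250\]. Degenerate (constant) distance vectors
#' yield 250 with a warning: the distances are effectively deterministic.
#'
#' @param d vector of non-negative distances, length >= 3, positive mean.
#' @return Integer degrees of freedom in \[1, 250\].
#' @export
dof_estimate <- function(d) {
  if (length(d) < 3L) stop("need at least 3 distances")
  m <- mean(d)
  if (!(m > 0)) stop("distances must have positive mean")
  v <- stats::var(d)
  if (v == 0) {
    warning("constant distances: degrees of freedom set to the cap (250)")
    return(250L)
  }
  as.integer(min(max(round(2 * m^2 / v), 1), 250))
}

#' Fit a DD-SIMCA one-class model
#'
#' Models the target class (pure almond) with an `ncomp`-component PCA of the
#' centered training spectra. Each sample gets a score distance `h` (leverage:
#' squared scores normalized by the per-component eigenvalues) and an
#' orthogonal distance `v` (squared residual norm). Both are treated as
#' scaled chi-square variables with data-driven degrees of freedom `Nh`, `Nv`
#' (moment estimates), giving the total distance
#' `c = Nh * h / h0 + Nv * v / v0 ~ chi2(Nh + Nv)`. The acceptance boundary
#' is the `1 - alpha` chi-square quantile; the outlier boundary uses the
#' order-statistic correction `(1 - gamma)^(1/n)` so a clean training set of
#' size `n` triggers an outlier call with probability about `gamma`.
#'
#' @param X_target `spectral_set` or matrix of target-class spectra.
#' @param ncomp number of principal components `A` (1 <= A < n).
#' @param alpha significance level of the acceptance boundary (default 0.01).
#' @param gamma outlier significance level (default 0.01, must be <= alpha).
#' @param preprocess optional [preprocess_spec()]; fitted on `X_target` and
#'   applied before modelling (and to any spectra scored later).
#' @return Object of class `ddsimca` with the PCA basis, normalizers,
#'   degrees of freedom, cutoffs `c_crit`/`c_out`, and training distances.
#' @export
ddsimca_fit <- function(X_target, ncomp, alpha = 0.01, gamma = 0.01,
                        preprocess = NULL) {
  if (!(gamma > 0 && gamma <= alpha && alpha < 0.5)) {
    stop("need 0 < gamma <= alpha < 0.5")
  }
  ids <- NULL
  if (!is.null(preprocess)) {
    preprocess <- fit_preprocess(preprocess, X_target)
    X_target <- apply_preprocess(preprocess, X_target)
  }
  if (inherits(X_target, "spectral_set")) {
    ids <- X_target$meta$specimen_id
    X <- X_target$spectra
  } else X <- as.matrix(X_target)
  n <- nrow(X); J <- ncol(X)
  ncomp <- as.integer(ncomp)
  if (!(ncomp >= 1L && ncomp < n)) stop("need 1 <= ncomp < n_train")

  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  sv <- svd(Xc)
  rank <- sum(sv$d > sv$d[1] * 1e-10)
  if (ncomp >= rank || sv$d[ncomp] <= sv$d[1] * 1e-10) {
    stop("ncomp reaches or exceeds the rank of the centered training matrix")
  }
  loadings <- sv$v[, seq_len(ncomp), drop = FALSE]
  eigenvalues <- sv$d[seq_len(ncomp)]^2 / (n - 1)
  scores <- Xc %*% loadings
  h <- rowSums(sweep(scores^2, 2, eigenvalues, `/`))
  resid <- Xc - scores %*% t(loadings)
  v <- rowSums(resid^2)
  h0 <- mean(h); v0 <- mean(v)
  if (!(v0 > 0)) {
    stop("zero mean orthogonal distance: the basis captures everything (over-fitted)")
  }
  Nh <- dof_estimate(h); Nv <- dof_estimate(v)
  cdist <- Nh * h / h0 + Nv * v / v0
  c_crit <- stats::qchisq(1 - alpha, Nh + Nv)
  c_out <- stats::qchisq((1 - gamma)^(1 / n), Nh + Nv)
  model <- structure(
    list(center = center, loadings = loadings, eigenvalues = eigenvalues,
         ncomp = ncomp, h0 = h0, v0 = v0, Nh = Nh, Nv = Nv,
         alpha = alpha, gamma = gamma, n_train = n,
         c_crit = c_crit, c_out = c_out, preprocess = preprocess,
         wavelengths = if (inherits(X_target, "spectral_set"))
           X_target$wavelengths else NULL),
    class = "ddsimca")
  model$training <- ddsimca_records(model, h, v, cdist, ids, mode = "train")
  model
}

#' @export
print.ddsimca <- function(x, ...) {
  cat(sprintf(paste0("<ddsimca> A=%d, n=%d, Nh=%d, Nv=%d, alpha=%g, ",
                     "gamma=%g, c_crit=%.3f, c_out=%.3f\n"),
              x$ncomp, x$n_train, x$Nh, x$Nv, x$alpha, x$gamma,
              x$c_crit, x$c_out))
  invisible(x)
}

# assemble a distance-record data frame with decisions
ddsimca_records <- function(model, h, v, cdist, ids, mode) {
  decision <- if (mode == "train") {
    ifelse(cdist > model$c_out, "outlier",
           ifelse(cdist > model$c_crit, "extreme", "regular"))
  } else {
    ifelse(cdist <= model$c_crit, "accepted", "rejected")
  }
  data.frame(
    specimen_id = if (is.null(ids)) sprintf("s%04d", seq_along(h)) else ids,
    h = h, v = v, c = cdist, decision = decision,
    stringsAsFactors = FALSE
  )
}

#' Score and orthogonal distances of new spectra
#'
#' Computes `h`, `v` and the total distance `c` against the trained center,
#' basis and normalizers; nothing is refitted. If the model embeds a
#' pretreatment it is applied first.
#'
#' @param model a fitted [ddsimca_fit()] model.
#' @param X `spectral_set` or matrix.
#' @return data.frame with `specimen_id`, `h`, `v`, `c`.
#' @export
ddsimca_distances <- function(model, X) {
  stopifnot(inherits(model, "ddsimca"))
  if (!is.null(model$preprocess)) X <- apply_preprocess(model$preprocess, X)
  ids <- NULL
  if (inherits(X, "spectral_set")) {
    ids <- X$meta$specimen_id
    X <- X$spectra
  } else X <- as.matrix(X)
  if (ncol(X) != length(model$center)) {
    stop("band count does not match the trained model")
  }
  Xc <- sweep(X, 2, model$center)
  scores <- Xc %*% model$loadings
  h <- rowSums(sweep(scores^2, 2, model$eigenvalues, `/`))
  v <- rowSums((Xc - scores %*% t(model$loadings))^2)
  cdist <- model$Nh * h / model$h0 + model$Nv * v / model$v0
  ddsimca_records(model, h, v, cdist, ids, mode = "none")[, 1:4]
}

#' Classify spectra against the target class
#'
#' Prediction mode: `accepted` iff `c <= c_crit` (boundary inclusive), else
#' `rejected`. Training mode grades samples as `regular` (`c <= c_crit`),
#' `extreme` (`c_crit < c <= c_out`) or `outlier` (`c > c_out`).
#'
#' @param model a fitted `ddsimca` model.
#' @param X `spectral_set` or matrix.
#' @param mode `"predict"` or `"train"`.
#' @return data.frame of distance records with a `decision` column.
#' @export
ddsimca_classify <- function(model, X, mode = c("predict", "train")) {
  mode <- match.arg(mode)
  rec <- ddsimca_distances(model, X)
  out <- ddsimca_records(model, rec$h, rec$v, rec$c, rec$specimen_id,
                         mode = if (mode == "train") "train" else "predict")
  out
}

#' Extreme-plot data
#'
#' For each significance level `a` on a grid, the expected number of training
#' samples beyond the `1 - a` chi-square boundary is `a * n`; the observed
#' count and a `+/- 2 * sqrt(a * n * (1 - a))` tolerance envelope let the
#' model's distributional assumption be checked visually.
#'
#' @param model a fitted `ddsimca` model.
#' @param X target-class spectra (default: the training records are used).
#' @param levels grid of significance levels.
#' @return data.frame with `level`, `expected`, `observed`, `envelope`.
#' @export
extreme_plot_data <- function(model, X = NULL,
                              levels = seq(0.01, 0.25, by = 0.01)) {
  stopifnot(inherits(model, "ddsimca"))
  cdist <- if (is.null(X)) model$training$c else ddsimca_distances(model, X)$c
  n <- length(cdist)
  dof <- model$Nh + model$Nv
  data.frame(
    level = levels,
    expected = levels * n,
    observed = vapply(levels, function(a)
      sum(cdist > stats::qchisq(1 - a, dof)), numeric(1)),
    envelope = 2 * sqrt(levels * n * (1 - levels))
  )
}

#' Select the number of DD-SIMCA components
#'
#' Fits models with `A = 1..A_max` and returns the `A` whose observed number
#' of extreme training samples at level `alpha` is closest to the expected
#' `alpha * n` (the factor count at which the chi-square description of the
#' training distances is most consistent). Ties break toward smaller `A`.
#'
#' @inheritParams ddsimca_fit
#' @param A_max largest component count to try (`< n_train`).
#' @return Selected integer `A`.
#' @export
ddsimca_select_factors <- function(X_target, A_max, alpha = 0.01,
                                   gamma = 0.01, preprocess = NULL) {
  if (!is.null(preprocess)) {
    preprocess <- fit_preprocess(preprocess, X_target)
    X_target <- apply_preprocess(preprocess, X_target)
  }
  n <- if (inherits(X_target, "spectral_set")) nrow(X_target$spectra)
       else nrow(as.matrix(X_target))
  if (A_max >= n) stop("A_max must be below n_train")
  score <- rep(Inf, A_max)
  for (A in seq_len(A_max)) {
    m <- try(ddsimca_fit(X_target, A, alpha, gamma), silent = TRUE)
    if (inherits(m, "try-error")) break
    observed <- sum(m$training$c > m$c_crit)
    score[A] <- abs(observed - alpha * n)
  }
  which.min(score)  # first minimum: ties go to the smaller A
}

#' Save / load a DD-SIMCA model as YAML
#'
#' @param model a `ddsimca` model.
#' @param path output path (conventionally `.ddsimca`).
#' @return `path` invisibly; `load_ddsimca()` returns the model.
#' @export
save_ddsimca <- function(model, path) {
  stopifnot(inherits(model, "ddsimca"))
  lst <- list(
    type = "ddsimca",
    center = as.numeric(model$center),
    loadings = apply(model$loadings, 2, as.numeric, simplify = FALSE),
    eigenvalues = as.numeric(model$eigenvalues),
    ncomp = model$ncomp, h0 = model$h0, v0 = model$v0,
    Nh = model$Nh, Nv = model$Nv, alpha = model$alpha, gamma = model$gamma,
    n_train = model$n_train, c_crit = model$c_crit, c_out = model$c_out,
    wavelengths = if (is.null(model$wavelengths)) NULL
                  else as.numeric(model$wavelengths),
    preprocess = if (is.null(model$preprocess)) NULL
                 else preprocess_to_list(model$preprocess)
  )
  yaml::write_yaml(lst, path, precision = 17L)
  invisible(path)
}

#' @rdname save_ddsimca
#' @export
load_ddsimca <- function(path) {
  lst <- yaml::read_yaml(path)
  if (is.null(lst$type) || lst$type != "ddsimca") stop("not a ddsimca model file")
  model <- structure(
    list(center = as.numeric(lst$center),
         loadings = do.call(cbind, lapply(lst$loadings, as.numeric)),
         eigenvalues = as.numeric(lst$eigenvalues),
         ncomp = as.integer(lst$ncomp), h0 = lst$h0, v0 = lst$v0,
         Nh = as.integer(lst$Nh), Nv = as.integer(lst$Nv),
         alpha = lst$alpha, gamma = lst$gamma,
         n_train = as.integer(lst$n_train),
         c_crit = lst$c_crit, c_out = lst$c_out,
         wavelengths = if (is.null(lst$wavelengths)) NULL
                       else as.numeric(lst$wavelengths),
         preprocess = if (is.null(lst$preprocess)) NULL
                      else preprocess_from_list(lst$preprocess)),
    class = "ddsimca")
  model
}
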