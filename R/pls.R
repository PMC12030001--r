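#' Fit a single-response PLS model (NIPALS)
#'
#' Deterministic NIPALS PLS1: predictors are mean-centred (and, if
#' \code{scale = TRUE}, scaled to unit variance), the response is
#' mean-centred, and latent variables are extracted one at a time by the
#' classical weight/score/loading/deflation recursion. Regression
#' coefficient vectors are stored for every component count so that a
#' k-component prediction needs no refit. Intended use: collinear
#' spectral-type predictors (JIP-test parameter sets, raw transient
#' curves) against one agronomic trait.
#'
#' @param X numeric matrix or data.frame of predictors, rows =
#'   observations.
#' @param y numeric response, \code{length(y) == nrow(X)}.
#' @param ncomp number of latent variables, at most
#'   \code{min(nrow(X) - 1, ncol(X))}.
#' @param scale logical; autoscale predictors to unit variance. A
#'   constant column under \code{scale = TRUE} gets scale 1 with a
#'   warning.
#' @return a \linkS4class{PLSFit}.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(60), 20, 3); y <- X %*% c(1, -1, 0.5) + rnorm(20, 0, .1)
#' fit <- fitPLS(X, y, ncomp = 3)
#' head(predict(fit, X))
#' @export
fitPLS <- function(X, y, ncomp, scale = FALSE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (n != length(y)) stop("nrow(X) must equal length(y)")
  if (n < 2L) stop("need at least 2 observations")
  if (stats::sd(y) == 0) stop("constant response")
  ncomp <- as.integer(ncomp)
  if (ncomp < 1L || ncomp > min(n - 1L, p))
    stop("ncomp must be in 1..min(nrow - 1, ncol)")
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(p))
  xc <- colMeans(X)
  if (scale) {
    xs <- apply(X, 2, stats::sd)
    if (any(xs == 0)) {
      warning("constant predictor column(s) with scale = TRUE; scale set to 1: ",
              paste(colnames(X)[xs == 0], collapse = ", "))
      xs[xs == 0] <- 1
    }
  } else xs <- rep(1, p)
  yc <- mean(y)
  Xc <- sweep(sweep(X, 2, xc), 2, xs, `/`)
  yr <- y - yc
  W <- P <- matrix(0, p, ncomp)
  Q <- numeric(ncomp)
  Tm <- matrix(0, n, ncomp)
  k_eff <- 0L
  for (k in seq_len(ncomp)) {
    w <- crossprod(Xc, yr)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break        # response variance exhausted
    w <- w / nw
    t <- drop(Xc %*% w)
    tt <- sum(t^2)
    if (tt < 1e-12) break
    pk <- drop(crossprod(Xc, t)) / tt
    qk <- sum(yr * t) / tt
    Xc <- Xc - tcrossprod(t, pk)
    yr <- yr - qk * t
    W[, k] <- w; P[, k] <- pk; Q[k] <- qk; Tm[, k] <- t
    k_eff <- k
  }
  if (k_eff < ncomp) {
    W <- W[, seq_len(k_eff), drop = FALSE]
    P <- P[, seq_len(k_eff), drop = FALSE]
    Tm <- Tm[, seq_len(k_eff), drop = FALSE]
    Q <- Q[seq_len(k_eff)]
  }
  R <- W %*% backsolve(crossprod(P, W), diag(k_eff), upper.tri = TRUE)
  B <- vapply(seq_len(k_eff), function(k)
    drop(R[, seq_len(k), drop = FALSE] %*% Q[seq_len(k)]), numeric(p))
  B <- matrix(B, nrow = p)
  dimnames(W) <- dimnames(P) <- dimnames(R) <- dimnames(B) <-
    list(colnames(X), paste0("LV", seq_len(k_eff)))
  methods::new("PLSFit", ncomp = k_eff,
               xCenter = setNames(xc, colnames(X)), xScale = xs,
               yCenter = yc, weights = W, xLoadings = P, yLoadings = Q,
               rotation = R, coefficients = B, scores = Tm)
}

#' Predict from a fitted PLS model
#'
#' Computes yhat = y_center + ((X_new - x_center)/x_scale) b_k. With
#' \code{k = 0} every prediction is the training-response mean. When
#' \code{newdata} has column names they are matched against the training
#' predictors; unknown columns raise an error listing them.
#'
#' @param object a \linkS4class{PLSFit}.
#' @param newdata matrix or data.frame of predictors.
#' @param k component count, \code{0..object@ncomp} (default: all).
#' @return numeric vector of predictions.
#' @export
setMethod("predict", "PLSFit", function(object, newdata,
                                        k = object@ncomp) {
  X <- as.matrix(newdata)
  k <- as.integer(k)
  if (k < 0L || k > object@ncomp)
    stop("k must be in 0..", object@ncomp)
  vars <- names(object@xCenter)
  if (!is.null(colnames(X))) {
    unknown <- setdiff(colnames(X), vars)
    if (length(unknown))
      stop("unknown predictor columns: ", paste(unknown, collapse = ", "))
    miss <- setdiff(vars, colnames(X))
    if (length(miss))
      stop("missing predictor columns: ", paste(miss, collapse = ", "))
    X <- X[, vars, drop = FALSE]
  } else if (ncol(X) != length(vars))
    stop("newdata must have ", length(vars), " columns")
  if (k == 0L) return(rep(object@yCenter, nrow(X)))
  Z <- sweep(sweep(X, 2, object@xCenter), 2, object@xScale, `/`)
  drop(object@yCenter + Z %*% object@coefficients[, k])
})

#' Cross-validated RMSEP curve
#'
#' Partitions the rows into \code{folds} random near-equal folds by
#' \code{seed}, fits PLS on each training complement, and reports the
#' root mean square error of prediction on the pooled out-of-fold
#' residuals for every component count 0..\code{maxComp} (component 0 is
#' the per-fold training-mean model). Rows are expected to be plot-level
#' records, so fold randomisation operates at plot level.
#'
#' @inheritParams fitPLS
#' @param maxComp largest component count to evaluate; the default
#'   \code{min(nrow(X) - ceiling(nrow(X)/folds) - 1, ncol(X))} is the
#'   largest count estimable in every fold. Larger requests are
#'   truncated with a warning.
#' @param folds number of folds (default 10).
#' @param seed integer seed controlling fold assignment.
#' @return an \linkS4class{RMSEPCurve}; its \code{selected} slot is the
#'   [selectComponents()] choice. The matrix of out-of-fold predictions
#'   (rows x component counts 0..maxComp) is attached as attribute
#'   \code{"cvPredictions"} of the \code{rmsep} slot... see
#'   [cvPredictions()].
#' @export
crossValidate <- function(X, y, maxComp = NULL, folds = 10L, seed,
                          scale = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X)
  folds <- as.integer(folds)
  if (folds < 2L) stop("folds must be >= 2")
  if (n < folds) stop("need at least as many rows as folds")
  cap <- min(n - ceiling(n / folds) - 1L, ncol(X))
  if (is.null(maxComp)) maxComp <- cap
  if (maxComp > cap) {
    warning("maxComp truncated to ", cap)
    maxComp <- cap
  }
  maxComp <- as.integer(maxComp)
  set.seed(as.integer(seed))
  assign <- sample(rep(seq_len(folds), length.out = n))
  pred <- matrix(NA_real_, n, maxComp + 1L,
                 dimnames = list(NULL, as.character(0:maxComp)))
  for (f in seq_len(folds)) {
    test <- which(assign == f)
    train <- which(assign != f)
    fit <- fitPLS(X[train, , drop = FALSE], y[train], ncomp = maxComp,
                  scale = scale)
    pred[test, 1L] <- mean(y[train])
    for (k in seq_len(fit@ncomp))
      pred[test, k + 1L] <- predict(fit, X[test, , drop = FALSE], k = k)
    if (fit@ncomp < maxComp)   # exhausted early: constant beyond
      for (k in seq(fit@ncomp + 1L, maxComp))
        pred[test, k + 1L] <- pred[test, fit@ncomp + 1L]
  }
  rmsep <- sqrt(colMeans((y - pred)^2))
  sel <- as.integer(which.min(rmsep[-1L]))
  curve <- methods::new("RMSEPCurve", rmsep = rmsep,
                        folds = assign, seed = as.integer(seed),
                        selected = sel)
  attr(curve@rmsep, "cvPredictions") <- pred
  curve
}

#' Out-of-fold prediction matrix of a cross-validation run
#'
#' @param curve an [crossValidate()] result.
#' @param k component count; default the selected one.
#' @return numeric vector of out-of-fold predictions at \code{k}
#'   components (or the full matrix when \code{k = NULL}).
#' @export
cvPredictions <- function(curve, k = curve@selected) {
  pred <- attr(curve@rmsep, "cvPredictions")
  if (is.null(pred)) stop("curve carries no prediction matrix")
  if (is.null(k)) return(pred)
  pred[, as.character(k)]
}

#' Select the latent-variable count from an RMSEP curve
#'
#' Smallest component count (>= 1) attaining the minimum RMSEP; ties
#' break toward fewer components.
#'
#' @param curve an \linkS4class{RMSEPCurve}, or a bare numeric vector of
#'   RMSEP values indexed by component count starting at 1.
#' @return integer component count.
#' @export
selectComponents <- function(curve) {
  v <- if (methods::is(curve, "RMSEPCurve")) curve@rmsep[-1L] else
    as.numeric(curve)
  if (!length(v)) stop("empty RMSEP curve")
  as.integer(which.min(v))
}

#' Percent variance explained by predictions
#'
#' 100 times the squared Pearson correlation between observed values and
#' predictions. With cross-validated predictions this is the
#' out-of-sample explained variance of the calibrated model.
#'
#' @param y observed values.
#' @param y_pred predicted values, same length (>= 3).
#' @return percentage in [0, 100], or \code{NA} with a warning when
#'   either vector has zero variance.
#' @export
explainedVariance <- function(y, y_pred) {
  if (length(y) != length(y_pred) || length(y) < 3L)
    stop("y and y_pred must have equal length >= 3")
  if (stats::sd(y) == 0 || stats::sd(y_pred) == 0) {
    warning("zero variance; explained variance undefined")
    return(NA_real_)
  }
  100 * stats::cor(y, y_pred)^2
}
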