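#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames rowData colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats coef cor lm median na.omit pt qt quantile rnorm runif sd
#'   setNames var predict
#' @importFrom utils read.csv write.csv head
NULL

#' FluorTransientSet: a set of OJIP fluorescence induction curves
#'
#' Container for dark-adapted chlorophyll-a fluorescence induction
#' transients, one column per measured plant. It extends
#' \linkS4class{SummarizedExperiment}: the single assay
#' \code{"fluorescence"} is a timepoints-by-samples matrix of raw
#' fluorescence readings (arbitrary instrument units), \code{rowData}
#' carries the acquisition time grid in seconds (\code{time_s}, strictly
#' increasing, quasi-logarithmic as exported by plant-efficiency
#' analysers), and \code{colData} carries the trial keys
#' \code{genotype}, \code{year}, \code{rep} and \code{plant}.
#'
#' @slot ... see \linkS4class{SummarizedExperiment}
#' @seealso [fluorTransientSet()] for construction,
#'   [extractLandmarks()], [jipTable()] for downstream analysis.
#' @export
setClass("FluorTransientSet", contains = "SummarizedExperiment")

setValidity("FluorTransientSet", function(object) {
  msg <- character()
  if (!"fluorescence" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'fluorescence' is required")
  rd <- SummarizedExperiment::rowData(object)
  if (!"time_s" %in% colnames(rd)) {
    msg <- c(msg, "rowData must contain 'time_s'")
  } else {
    tt <- rd$time_s
    if (any(!is.finite(tt)) || any(diff(tt) <= 0))
      msg <- c(msg, "time_s must be finite and strictly increasing")
  }
  cd <- SummarizedExperiment::colData(object)
  need <- c("genotype", "year", "rep", "plant")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste0("colData missing key columns: ",
                         paste(miss, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a FluorTransientSet
#'
#' @param times numeric vector of acquisition times in seconds, strictly
#'   increasing.
#' @param values numeric matrix of fluorescence readings,
#'   \code{length(times)} rows, one column per measured plant. Values must
#'   be finite and positive.
#' @param keys data.frame with one row per column of \code{values} and
#'   columns \code{genotype}, \code{year}, \code{rep}, \code{plant}.
#' @return a \linkS4class{FluorTransientSet}.
#' @examples
#' tt <- ojipTimeGrid(10)
#' f  <- matrix(200 + 800 * (1 - exp(-tt / 0.03)), ncol = 1)
#' keys <- data.frame(genotype = "H1", year = 2017L, rep = 1L, plant = 1L)
#' fluorTransientSet(tt, f, keys)
#' @export
fluorTransientSet <- function(times, values, keys) {
  values <- as.matrix(values)
  if (nrow(values) != length(times))
    stop("nrow(values) must equal length(times)")
  if (nrow(keys) != ncol(values))
    stop("keys must have one row per transient")
  if (any(!is.finite(values)) || any(values <= 0))
    stop("fluorescence values must be finite and positive")
  cd <- S4Vectors::DataFrame(keys)
  cd$sample_id <- sprintf("%s_y%s_r%s_p%s", keys$genotype, keys$year,
                          keys$rep, keys$plant)
  colnames(values) <- cd$sample_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(fluorescence = values),
    rowData = S4Vectors::DataFrame(time_s = as.numeric(times)),
    colData = cd)
  methods::new("FluorTransientSet", se)
}

#' Accessors for FluorTransientSet
#'
#' \code{fluorTimes} returns the acquisition time grid in seconds;
#' \code{fluorValues} the timepoints-by-samples fluorescence matrix;
#' \code{sampleKeys} the genotype/year/rep/plant key table as a
#' data.frame.
#'
#' @param x a \linkS4class{FluorTransientSet}.
#' @return see description.
#' @export
fluorTimes <- function(x) SummarizedExperiment::rowData(x)$time_s

#' @rdname fluorTimes
#' @export
fluorValues <- function(x) SummarizedExperiment::assay(x, "fluorescence")

#' @rdname fluorTimes
#' @export
sampleKeys <- function(x) {
  as.data.frame(SummarizedExperiment::colData(x))
}

setMethod("show", "FluorTransientSet", function(object) {
  tt <- fluorTimes(object)
  cat("FluorTransientSet with", ncol(object), "transients x",
      nrow(object), "timepoints\n")
  cat(sprintf("  time grid: %.0f us .. %.3g s\n", tt[1] * 1e6, tt[length(tt)]))
  ks <- sampleKeys(object)
  cat("  genotypes:", length(unique(ks$genotype)),
      " years:", length(unique(ks$year)),
      " reps:", length(unique(ks$rep)), "\n")
})

#' PLSFit: a fitted single-response partial least squares model
#'
#' Holds the NIPALS PLS1 factorisation of a centred (optionally
#' autoscaled) predictor matrix against one response: predictor weights
#' \code{W}, predictor loadings \code{P}, response loadings \code{q}, the
#' rotation \code{R = W (P'W)^-1} used for direct score computation, and
#' regression coefficient vectors for every component count up to
#' \code{ncomp}. Scores of the training data are mutually orthogonal.
#'
#' @slot ncomp integer, number of extracted latent variables.
#' @slot xCenter,xScale numeric vectors (length = predictors) used to
#'   centre/scale new data; \code{xScale} is all ones when fitted
#'   unscaled.
#' @slot yCenter numeric scalar, training-response mean.
#' @slot weights,xLoadings,rotation predictor-by-component matrices.
#' @slot yLoadings numeric vector, length \code{ncomp}.
#' @slot coefficients predictor-by-component matrix; column k holds the
#'   coefficient vector of the k-component model on the centred/scaled
#'   predictor scale.
#' @slot scores training score matrix (rows by components).
#' @export
setClass("PLSFit", representation(
  ncomp = "integer", xCenter = "numeric", xScale = "numeric",
  yCenter = "numeric", weights = "matrix", xLoadings = "matrix",
  yLoadings = "numeric", rotation = "matrix", coefficients = "matrix",
  scores = "matrix"))

setValidity("PLSFit", function(object) {
  p <- length(object@xCenter)
  k <- object@ncomp
  ok <- nrow(object@weights) == p && ncol(object@weights) == k &&
    identical(dim(object@coefficients), c(p, k)) &&
    length(object@yLoadings) == k && length(object@xScale) == p
  if (!ok) "inconsistent factor matrix dimensions" else TRUE
})

setMethod("show", "PLSFit", function(object) {
  cat("PLSFit:", length(object@xCenter), "predictors,",
      object@ncomp, "latent variables\n")
})

#' RMSEPCurve: cross-validated prediction error by component count
#'
#' Root mean square error of prediction from k-fold cross-validation,
#' indexed by latent-variable count (component 0 = per-fold mean model).
#' RMSEP is computed on the pooled out-of-fold residuals.
#'
#' @slot rmsep named numeric vector, entries \code{"0"..."<max k>"}.
#' @slot folds integer vector of fold assignments, one per training row.
#' @slot seed integer seed that produced the fold assignment.
#' @slot selected integer, smallest component count attaining the minimum
#'   RMSEP (component counts >= 1 only).
#' @export
setClass("RMSEPCurve", representation(
  rmsep = "numeric", folds = "integer", seed = "integer",
  selected = "integer"))

setValidity("RMSEPCurve", function(object) {
  if (any(object@rmsep < 0)) return("RMSEP values must be nonnegative")
  TRUE
})

setMethod("show", "RMSEPCurve", function(object) {
  k <- object@selected
  cat(sprintf("RMSEPCurve: %d components, minimum %.4g at %d LV (seed %d)\n",
              length(object@rmsep) - 1L, object@rmsep[as.character(k)],
              k, object@seed))
})

#' VarianceComponents: EMS variance components of one trait
#'
#' Method-of-moments (expected mean squares) decomposition of a balanced
#' multi-year trial into genotypic, environmental (year), genotype-by-year
#' and residual variance, with the design sizes needed for progeny-mean
#' heritability and a delete-one-genotype jackknife standard error of
#' heritability.
#'
#' @slot trait character, trait name.
#' @slot sigma2G,sigma2E,sigma2GxE,sigma2e numeric, components in squared
#'   trait units (truncated at zero).
#' @slot nE,nR integer, number of environments (years) and replicates.
#' @slot seH2 numeric, jackknife SE of heritability (NA if not computed).
#' @export
setClass("VarianceComponents", representation(
  trait = "character", sigma2G = "numeric", sigma2E = "numeric",
  sigma2GxE = "numeric", sigma2e = "numeric", nE = "integer",
  nR = "integer", seH2 = "numeric"))

setValidity("VarianceComponents", function(object) {
  v <- c(object@sigma2G, object@sigma2E, object@sigma2GxE, object@sigma2e)
  if (any(v < 0, na.rm = TRUE)) return("variance components must be >= 0")
  if (object@nE < 1L || object@nR < 1L) return("nE and nR must be >= 1")
  TRUE
})

#' Construct a VarianceComponents object directly
#'
#' Mostly useful for evaluating heritability on published component
#' values; [estimateVarianceComponents()] builds one from plot data.
#'
#' @param sigma2G,sigma2GxE,sigma2e,sigma2E variance components (squared
#'   trait units); \code{sigma2E} may be NA when only heritability is
#'   needed.
#' @param nE,nR environments and replicates.
#' @param trait optional trait label.
#' @param seH2 optional jackknife SE of heritability.
#' @return a \linkS4class{VarianceComponents}.
#' @examples
#' vc <- varianceComponents(1.296, 2.209, 0.795, nE = 3, nR = 4)
#' heritability(vc)
#' @export
varianceComponents <- function(sigma2G, sigma2GxE, sigma2e, sigma2E = NA_real_,
                               nE = 3L, nR = 4L, trait = "", seH2 = NA_real_) {
  methods::new("VarianceComponents", trait = trait,
               sigma2G = as.numeric(sigma2G), sigma2E = as.numeric(sigma2E),
               sigma2GxE = as.numeric(sigma2GxE), sigma2e = as.numeric(sigma2e),
               nE = as.integer(nE), nR = as.integer(nR),
               seH2 = as.numeric(seH2))
}

setMethod("show", "VarianceComponents", function(object) {
  cat(sprintf("VarianceComponents%s: s2G=%.4g s2E=%.4g s2GxE=%.4g s2e=%.4g (nE=%d, nR=%d)\n",
              if (nzchar(object@trait)) paste0(" [", object@trait, "]") else "",
              object@sigma2G, object@sigma2E, object@sigma2GxE,
              object@sigma2e, object@nE, object@nR))
  h2 <- tryCatch(heritability(object), error = function(e) NA_real_)
  if (is.finite(h2))
    cat(sprintf("  progeny-mean H2 = %.3f%s\n", h2,
                if (is.finite(object@seH2))
                  sprintf(" +/- %.3f", object@seH2) else ""))
})
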