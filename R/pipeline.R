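#' Run the full fluorescence-based selection pipeline
#'
#' Orchestrates the complete analysis: simulate (or ingest) a
#' multi-year trial, derive the JIP-test parameter table and plot-mean
#' transient curves, fit a cross-validated PLS model for every requested
#' trait x predictor-set combination, select the latent-variable count by
#' minimum RMSEP, attach the out-of-fold predictions as new plot-level
#' traits, push observed and predicted traits through the
#' variance-component / heritability / genetic-correlation estimators,
#' and compute the efficiency of indirect selection on each predicted
#' trait. All intermediate tables are written as CSV and the report as
#' JSON; reruns with an identical configuration are byte-identical.
#'
#' Configuration fields (all optional unless noted):
#' \describe{
#'   \item{mode}{\code{"simulate"} (default) or \code{"ingest"}.}
#'   \item{transients, agro}{CSV paths, required in ingest mode.}
#'   \item{traits}{subset of \code{c("gy", "gm")} (default both).}
#'   \item{predictor_sets}{subset of \code{c("parameters",
#'     "transients")} (default both). "parameters" uses the full
#'     58-entry biophysical roster; "transients" the raw plot-mean
#'     curves, mean-centred only.}
#'   \item{folds}{CV folds (default 10).}
#'   \item{seed_sim, seed_cv}{integer seeds (defaults 1 and 2).}
#'   \item{out_dir}{output directory; \code{NULL} skips file output.}
#'   \item{scale_parameters}{autoscale the parameter predictors
#'     (default TRUE; heterogeneous units).}
#' }
#'
#' @param config named list (see above) or path to a YAML file.
#' @return list of class \code{"selectionReport"}: \code{observed}
#'   (variance components, heritabilities, correlation tables),
#'   \code{models} (per combination: RMSEP curve, selected LVs, minimum
#'   RMSEP, percent variance explained, predicted-trait variance
#'   components, H2 +/- SE, rG +/- SE with the source trait, EI), and
#'   \code{config} (with seeds recorded).
#' @export
runPipeline <- function(config = list()) {
  if (is.character(config)) config <- readRunConfig(config)
  cfg <- utils::modifyList(list(
    mode = "simulate", traits = c("gy", "gm"),
    predictor_sets = c("parameters", "transients"),
    folds = 10L, seed_sim = 1L, seed_cv = 2L, out_dir = NULL,
    scale_parameters = TRUE), config)
  cfg$traits <- match.arg(cfg$traits, c("gy", "gm"), several.ok = TRUE)
  cfg$predictor_sets <- match.arg(cfg$predictor_sets,
                                  c("parameters", "transients"),
                                  several.ok = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## stage 1: obtain trial -------------------------------------------------
  if (cfg$mode == "simulate") {
    dcfg <- defaultTrialConfig()
    trial <- stage("simulate",
                   simulateTrial(dcfg$design, dcfg$effects, cfg$seed_sim))
    transients <- trial$transients
    agro <- trial$agro
  } else {
    transients <- stage("ingest", readTransientsCSV(cfg$transients))
    agro <- stage("ingest", read.csv(cfg$agro))
  }

  ## stage 2: fluorescence feature tables ----------------------------------
  jip_plot <- stage("jip", jipTable(transients, level = "plot"))
  trans_plot <- stage("jip", transientPlotMeans(transients))
  tbl <- stage("trial_table", trialTable(agro, jip_plot))

  ## stage 3: observed-trait quantitative genetics -------------------------
  obs_traits <- intersect(c("gy", "gm", "fvfm", "piabs"), names(tbl))
  vc_obs <- lapply(setNames(obs_traits, obs_traits), function(tr)
    stage("quantgen", estimateVarianceComponents(tbl, tr)))
  h2_obs <- vapply(vc_obs, heritability, numeric(1))
  corr <- list()
  for (i in seq_along(obs_traits)) for (j in seq_along(obs_traits)) {
    if (i >= j) next
    key <- paste(obs_traits[i], obs_traits[j], sep = "~")
    corr[[key]] <- list(
      pearson = pearsonCor(tbl, obs_traits[i], obs_traits[j]),
      genetic = stage("quantgen",
                      geneticCovariance(tbl, obs_traits[i], obs_traits[j])))
  }

  ## stage 4: prediction models --------------------------------------------
  key_match <- interaction(tbl$genotype, tbl$year, tbl$rep, drop = TRUE)
  pm_keys <- interaction(jip_plot$genotype, jip_plot$year, jip_plot$rep,
                         drop = TRUE)
  tm_keys <- interaction(trans_plot$genotype, trans_plot$year,
                         trans_plot$rep, drop = TRUE)
  X_par <- as.matrix(jip_plot[match(key_match, pm_keys),
                              jipParameterNames("full58")])
  X_tra <- as.matrix(trans_plot[match(key_match, tm_keys),
                                grep("^t_", names(trans_plot))])
  models <- list()
  for (tr in cfg$traits) for (ps in cfg$predictor_sets) {
    X <- if (ps == "parameters") X_par else X_tra
    scale <- if (ps == "parameters") isTRUE(cfg$scale_parameters) else FALSE
    y <- tbl[[tr]]
    curve <- stage("cross_validate",
                   crossValidate(X, y, folds = cfg$folds,
                                 seed = cfg$seed_cv, scale = scale))
    k <- selectComponents(curve)
    yhat <- cvPredictions(curve, k)
    fit <- stage("fit", fitPLS(X, y, ncomp = k, scale = scale))
    pred_trait <- paste0(tr, "_", ps)
    tbl[[pred_trait]] <- yhat
    vc_pred <- stage("quantgen",
                     estimateVarianceComponents(tbl, pred_trait))
    gc <- stage("quantgen", geneticCovariance(tbl, pred_trait, tr))
    h2p <- heritability(vc_pred)
    ei <- if (is.finite(gc$rG) && is.finite(h2p) && h2p >= 0 &&
              is.finite(h2_obs[[tr]]) && h2_obs[[tr]] > 0)
      indirectSelectionEfficiency(gc$rG, h2p, h2_obs[[tr]])$EI
    else NA_real_
    models[[pred_trait]] <- list(
      trait = tr, predictor_set = ps,
      n_predictors = ncol(X), folds = cfg$folds, seed_cv = cfg$seed_cv,
      selected_lv = k,
      rmsep_min = unname(curve@rmsep[as.character(k)]),
      rmsep = curve@rmsep,
      variance_explained_pct = explainedVariance(y, yhat),
      variance_components = list(
        sigma2_G = vc_pred@sigma2G, sigma2_E = vc_pred@sigma2E,
        sigma2_GxE = vc_pred@sigma2GxE, sigma2_e = vc_pred@sigma2e),
      H2 = h2p, H2_se = vc_pred@seH2,
      rG_source = gc$rG, rG_se = gc$seRG,
      EI_pct = ei,
      fit = fit, curve = curve, predictions = yhat)
  }

  report <- structure(list(
    observed = list(
      variance_components = lapply(vc_obs, function(v) list(
        sigma2_G = v@sigma2G, sigma2_E = v@sigma2E,
        sigma2_GxE = v@sigma2GxE, sigma2_e = v@sigma2e,
        H2 = heritability(v), H2_se = v@seH2)),
      correlations = corr,
      anova = list(gy = anovaTrial(tbl, "gy"),
                   gm = anovaTrial(tbl, "gm"))),
    models = models,
    table = tbl,
    config = cfg), class = "selectionReport")

  if (!is.null(cfg$out_dir)) .write_report(report, jip_plot, trans_plot)
  report
}

.report_json <- function(report) {
  strip <- function(m) m[setdiff(names(m),
                                 c("fit", "curve", "predictions"))]
  list(config = report$config[c("mode", "traits", "predictor_sets",
                                "folds", "seed_sim", "seed_cv")],
       observed = report$observed["variance_components"],
       models = lapply(report$models, strip))
}

.write_report <- function(report, jip_plot, trans_plot) {
  dir <- report$config$out_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(jip_plot, file.path(dir, "jip_parameters_plot.csv"),
            row.names = FALSE)
  write.csv(trans_plot, file.path(dir, "transients_plot.csv"),
            row.names = FALSE)
  write.csv(report$table, file.path(dir, "trial_table.csv"),
            row.names = FALSE)
  for (nm in names(report$models)) {
    m <- report$models[[nm]]
    write.csv(data.frame(lv = as.integer(names(m$rmsep)),
                         rmsep = unname(m$rmsep)),
              file.path(dir, paste0("rmsep_", nm, ".csv")),
              row.names = FALSE)
    write.csv(data.frame(predictor = rownames(m$fit@coefficients),
                         coefficient = m$fit@coefficients[, m$fit@ncomp],
                         loading = m$fit@xLoadings[, m$fit@ncomp]),
              file.path(dir, paste0("coefficients_", nm, ".csv")),
              row.names = FALSE)
    write.csv(cbind(report$table[c("genotype", "year", "rep")],
                    observed = report$table[[m$trait]],
                    predicted = m$predictions),
              file.path(dir, paste0("predictions_", nm, ".csv")),
              row.names = FALSE)
  }
  jsonlite::write_json(.report_json(report),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.selectionReport <- function(x, ...) {
  cat("Fluorescence-based selection report\n")
  cat(sprintf("  %d plots, traits: %s\n", nrow(x$table),
              paste(x$config$traits, collapse = ", ")))
  for (nm in names(x$models)) {
    m <- x$models[[nm]]
    cat(sprintf("  %-18s LVs=%2d  RMSEP=%.3f  R2cv=%.1f%%  H2=%.2f  rG=%.2f  EI=%.1f%%\n",
                nm, m$selected_lv, m$rmsep_min, m$variance_explained_pct,
                m$H2, m$rG_source, m$EI_pct))
  }
  invisible(x)
}

#' Diagnostic figures for a selection report
#'
#' Writes, for each fitted model, the RMSEP-versus-latent-variable curve
#' with the selected minimum marked, the coefficient/loading profile
#' against predictor index, and the observed-versus-predicted scatter;
#' plus one bar chart of indirect-selection efficiencies. Missing
#' artifacts skip the corresponding plot with a warning.
#'
#' @param report a [runPipeline()] result.
#' @param dir output directory for the image files.
#' @param format device suffix, \code{"png"} or \code{"svg"}.
#' @return invisible character vector of files written.
#' @export
makeFigures <- function(report, dir, format = c("png", "svg")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  emit <- function(p, name, width = 6, height = 4) {
    f <- file.path(dir, paste0(name, ".", format))
    ggplot2::ggsave(f, p, width = width, height = height, dpi = 120)
    files <<- c(files, f)
  }
  for (nm in names(report$models)) {
    m <- report$models[[nm]]
    if (is.null(m$rmsep)) { warning("no RMSEP curve for ", nm); next }
    dcurve <- data.frame(lv = as.integer(names(m$rmsep)),
                         rmsep = unname(m$rmsep))
    p1 <- ggplot2::ggplot(dcurve[dcurve$lv > 0, ],
                          ggplot2::aes(.data$lv, .data$rmsep)) +
      ggplot2::geom_line() +
      ggplot2::geom_vline(xintercept = m$selected_lv, colour = "red") +
      ggplot2::labs(x = "latent variables", y = "RMSEP",
                    title = nm) +
      ggplot2::theme_minimal()
    emit(p1, paste0("rmsep_", nm))
    co <- m$fit@coefficients[, m$fit@ncomp]
    p2 <- ggplot2::ggplot(data.frame(index = seq_along(co), value = co),
                          ggplot2::aes(.data$index, .data$value)) +
      ggplot2::geom_col() +
      ggplot2::labs(x = "predictor index", y = "coefficient", title = nm) +
      ggplot2::theme_minimal()
    emit(p2, paste0("coefficients_", nm))
    dsc <- data.frame(observed = report$table[[m$trait]],
                      predicted = m$predictions)
    p3 <- ggplot2::ggplot(dsc, ggplot2::aes(.data$observed,
                                            .data$predicted)) +
      ggplot2::geom_point(alpha = 0.6) +
      ggplot2::geom_abline(slope = 1, intercept = 0,
                           linetype = "dashed") +
      ggplot2::labs(title = sprintf("%s (R2cv = %.1f%%)", nm,
                                    m$variance_explained_pct)) +
      ggplot2::theme_minimal()
    emit(p3, paste0("observed_vs_predicted_", nm))
  }
  ei <- vapply(report$models, function(m) m$EI_pct, numeric(1))
  if (length(ei)) {
    dei <- data.frame(model = names(ei), EI = unname(ei))
    p4 <- ggplot2::ggplot(dei, ggplot2::aes(.data$model, .data$EI)) +
      ggplot2::geom_col() +
      ggplot2::labs(y = "indirect selection efficiency (%)", x = NULL) +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                         hjust = 1))
    emit(p4, "selection_efficiency")
  }
  invisible(files)
}

#' @importFrom ggplot2 .data
NULL
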