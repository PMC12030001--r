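#' Standardise grain yield to 14 % moisture
#'
#' GY (t/ha) = (plot_weight_kg * (100 - moisture)/86 * 10000/plot_area) / 1000.
#'
#' @param plot_weight_kg harvested plot weight, kg.
#' @param sample_moisture_pct grain moisture of the sample, percent.
#' @param plot_area plot area in m2 (default 7).
#' @return grain yield in t/ha at 14 % moisture.
#' @export
gyStandardize <- function(plot_weight_kg, sample_moisture_pct,
                          plot_area = 7) {
  if (any(sample_moisture_pct >= 100 | sample_moisture_pct < 0))
    stop("moisture must be in [0, 100)")
  (plot_weight_kg * (100 - sample_moisture_pct) / 86 *
     (1e4 / plot_area)) / 1000
}

#' Assemble the plot-level trial table
#'
#' Merges the agronomic plot table with plot-mean fluorescence traits
#' (Fv/Fm = phi_Po and PI_ABS from [jipTable()] at plot level) into one
#' balanced table keyed by genotype, year, rep and block, ready for the
#' ANOVA / variance-component estimators.
#'
#' @param agro plot table with columns genotype, year, rep, block and
#'   trait columns (at least \code{gy_t_ha}, \code{gm_pct}).
#' @param jip_plot optional plot-level [jipTable()] output; its
#'   \code{phi_Po} and \code{PI_ABS} columns are attached as
#'   \code{fvfm} and \code{piabs}.
#' @return data.frame with columns genotype, year, rep, block, gy, gm
#'   and any fluorescence trait columns.
#' @export
trialTable <- function(agro, jip_plot = NULL) {
  need <- c("genotype", "year", "rep", "block", "gy_t_ha", "gm_pct")
  miss <- setdiff(need, names(agro))
  if (length(miss)) stop("agro table missing columns: ",
                         paste(miss, collapse = ", "))
  tbl <- data.frame(genotype = agro$genotype, year = agro$year,
                    rep = agro$rep, block = agro$block,
                    gy = agro$gy_t_ha, gm = agro$gm_pct)
  if (!is.null(jip_plot)) {
    m <- merge(tbl, jip_plot[c("genotype", "year", "rep",
                               "phi_Po", "PI_ABS")],
               by = c("genotype", "year", "rep"), all.x = TRUE)
    names(m)[names(m) == "phi_Po"] <- "fvfm"
    names(m)[names(m) == "PI_ABS"] <- "piabs"
    tbl <- m
  }
  tbl[order(tbl$year, tbl$rep, tbl$genotype), , drop = FALSE]
}

.check_balanced <- function(table) {
  cnt <- base::table(table$genotype, table$year, table$rep)
  if (any(cnt != 1L))
    stop("table is not balanced: every genotype x year x rep cell must ",
         "be present exactly once (EMS estimators require a complete ",
         "balanced layout)")
  invisible(TRUE)
}

#' Balanced multi-year trial ANOVA
#'
#' Sum-of-squares decomposition of a complete balanced randomized-block
#' multi-year trial into Genotype, Year, Replication-within-Year,
#' Block-within-Year, Genotype:Year and Error strata, using the standard
#' balanced-design (cell-mean) formulas. Degrees of freedom are
#' (g-1, e-1, e(r-1), e(b-1), (g-1)(e-1), remainder), summing to n-1.
#' F tests are against the error mean square.
#'
#' @param table a [trialTable()]-shaped data.frame (columns genotype,
#'   year, rep, block, plus trait columns).
#' @param trait name of the trait column to analyse.
#' @return data.frame of class \code{c("anovaTable", "data.frame")} with
#'   columns \code{source, df, ss, ms, F, p}.
#' @export
anovaTrial <- function(table, trait) {
  if (!trait %in% names(table)) stop("trait column '", trait, "' not found")
  .check_balanced(table)
  y <- table[[trait]]
  if (any(!is.finite(y))) stop("trait values must be finite")
  G <- factor(table$genotype); Y <- factor(table$year)
  Rp <- factor(table$rep); B <- factor(table$block)
  g <- nlevels(G); e <- nlevels(Y); r <- nlevels(Rp); b <- nlevels(B)
  n <- length(y)
  mu <- mean(y)
  m_g  <- tapply(y, G, mean)
  m_y  <- tapply(y, Y, mean)
  m_gy <- tapply(y, list(G, Y), mean)
  m_yr <- tapply(y, list(Y, Rp), mean)
  m_yb <- tapply(y, list(Y, B), mean)
  n_yb <- base::table(Y, B)
  if (length(unique(n_yb[n_yb > 0])) > 1L)
    stop("blocks must have equal size within year for the balanced ",
         "decomposition")
  ss_g <- e * r * sum((m_g - mu)^2)
  ss_y <- g * r * sum((m_y - mu)^2)
  ss_yr <- g * sum((sweep(m_yr, 1, m_y))^2)
  ss_yb <- sum(n_yb * (sweep(m_yb, 1, m_y))^2, na.rm = TRUE)
  ss_gy <- r * sum(sweep(sweep(m_gy, 1, m_g), 2, m_y - mu)^2)
  ss_t <- sum((y - mu)^2)
  ss_e <- ss_t - ss_g - ss_y - ss_yr - ss_yb - ss_gy
  df <- c(g - 1, e - 1, e * (r - 1), e * (b - 1),
          (g - 1) * (e - 1))
  df <- c(df, n - 1 - sum(df))
  ss <- c(ss_g, ss_y, ss_yr, ss_yb, ss_gy, ss_e)
  ms <- ss / df
  Fv <- c(ms[1:5] / ms[6], NA)
  p <- c(stats::pf(Fv[1:5], df[1:5], df[6], lower.tail = FALSE), NA)
  structure(data.frame(
    source = c("Genotype", "Year", "Replication(Year)", "Block(Year)",
               "Genotype:Year", "Error"),
    df = df, ss = ss, ms = ms, F = Fv, p = p,
    stringsAsFactors = FALSE),
    class = c("anovaTable", "data.frame"), trait = trait,
    design = c(g = g, e = e, r = r, b = b))
}

## EMS solution from the mean squares of an anovaTable (no truncation).
.ems_raw <- function(an) {
  d <- attr(an, "design")
  ms <- setNames(an$ms, an$source)
  list(sigma2e = ms[["Error"]],
       sigma2GxE = (ms[["Genotype:Year"]] - ms[["Error"]]) / d[["r"]],
       sigma2G = (ms[["Genotype"]] - ms[["Genotype:Year"]]) /
         (d[["e"]] * d[["r"]]),
       sigma2E = (ms[["Year"]] - ms[["Replication(Year)"]]) /
         (d[["g"]] * d[["r"]]),
       nE = d[["e"]], nR = d[["r"]])
}

#' Estimate variance components by expected mean squares
#'
#' Method-of-moments estimators on the balanced layout:
#' sigma2_e = MS_Error, sigma2_GxE = (MS_GxY - MS_Error)/nR,
#' sigma2_G = (MS_G - MS_GxY)/(nE nR),
#' sigma2_E = (MS_Year - MS_Rep(Year))/(nG nR); negative solutions are
#' truncated at zero. For balanced data these coincide in expectation
#' with the REML mixed-model estimates. The standard error of
#' heritability is a delete-one-genotype jackknife.
#'
#' @inheritParams anovaTrial
#' @param jackknife logical; compute the jackknife SE of heritability
#'   (default TRUE).
#' @return a \linkS4class{VarianceComponents}.
#' @export
estimateVarianceComponents <- function(table, trait, jackknife = TRUE) {
  an <- anovaTrial(table, trait)
  raw <- .ems_raw(an)
  if (raw$nE * raw$nR == 0) stop("nE * nR must be positive")
  tr0 <- function(v) max(0, v)
  seH2 <- NA_real_
  if (jackknife) {
    genos <- unique(table$genotype)
    g <- length(genos)
    if (g > 2L) {
      h <- vapply(genos, function(gg) {
        sub <- table[table$genotype != gg, , drop = FALSE]
        r <- .ems_raw(anovaTrial(sub, trait))
        .h2(tr0(r$sigma2G), tr0(r$sigma2GxE), tr0(r$sigma2e), r$nE, r$nR)
      }, numeric(1))
      seH2 <- sqrt((g - 1) / g * sum((h - mean(h))^2))
    }
  }
  varianceComponents(tr0(raw$sigma2G), tr0(raw$sigma2GxE),
                     tr0(raw$sigma2e), sigma2E = tr0(raw$sigma2E),
                     nE = raw$nE, nR = raw$nR, trait = trait, seH2 = seH2)
}

.h2 <- function(s2G, s2GxE, s2e, nE, nR) {
  den <- s2G + s2GxE / nE + s2e / (nE * nR)
  if (den <= 0) return(NA_real_)
  s2G / den
}

#' Progeny-mean heritability
#'
#' H2 = sigma2_G / (sigma2_G + sigma2_GxE/nE + sigma2_e/(nE nR)), the
#' fraction of entry-mean variance attributable to genotype given nE
#' environments and nR replicates. Returns a value in [0, 1]; when all
#' components are zero the ratio is undefined and \code{NA} is returned
#' with a warning.
#'
#' @param vc a \linkS4class{VarianceComponents}.
#' @return numeric heritability.
#' @examples
#' heritability(varianceComponents(1.296, 2.209, 0.795, nE = 3, nR = 4))
#' @export
setGeneric("heritability", function(vc) standardGeneric("heritability"))

#' @rdname heritability
#' @export
setMethod("heritability", "VarianceComponents", function(vc) {
  h <- .h2(vc@sigma2G, vc@sigma2GxE, vc@sigma2e, vc@nE, vc@nR)
  if (is.na(h)) warning("all variance components are zero; H2 undefined")
  h
})

#' Genetic covariance and genetic correlation of two traits
#'
#' Applies the expected-mean-square contrast to mean cross-products:
#' with MCP_G and MCP_GxY the genotype and genotype-by-year mean
#' cross-products of the two traits' deviations (mirroring the ANOVA
#' decomposition), CovG = (MCP_G - MCP_GxY)/(nE nR), and
#' rG = CovG / sqrt(sigmaG(X) sigmaG(Y)) with the (untruncated) EMS
#' genetic variances. If either genetic variance is nonpositive, rG is
#' undefined (\code{NA}, flagged by a warning, never clipped); values
#' outside [-1, 1] are reported as-is with a warning since sampling
#' noise can push the ratio past 1. The SE of rG is a
#' delete-one-genotype jackknife.
#'
#' @inheritParams anovaTrial
#' @param traitX,traitY trait column names.
#' @param jackknife logical; compute the jackknife SE (default TRUE).
#' @return list of class \code{"geneticCovariance"} with elements
#'   \code{traitX, traitY, covG, sigma2GX, sigma2GY, rG, seRG}.
#' @export
geneticCovariance <- function(table, traitX, traitY, jackknife = TRUE) {
  .check_balanced(table)
  comp <- function(tbl) {
    cXY <- .covG_ems(tbl, traitX, traitY)
    cXX <- .covG_ems(tbl, traitX, traitX)
    cYY <- .covG_ems(tbl, traitY, traitY)
    rG <- if (cXX <= 0 || cYY <= 0) NA_real_ else cXY / sqrt(cXX * cYY)
    list(covG = cXY, sXX = cXX, sYY = cYY, rG = rG)
  }
  full <- comp(table)
  if (is.na(full$rG))
    warning("nonpositive genetic variance; rG undefined")
  else if (abs(full$rG) > 1)
    warning("estimated |rG| exceeds 1 (reported unclipped)")
  seRG <- NA_real_
  if (jackknife && !is.na(full$rG)) {
    genos <- unique(table$genotype)
    g <- length(genos)
    rj <- vapply(genos, function(gg)
      comp(table[table$genotype != gg, , drop = FALSE])$rG, numeric(1))
    if (all(is.finite(rj)))
      seRG <- sqrt((g - 1) / g * sum((rj - mean(rj))^2))
  }
  structure(list(traitX = traitX, traitY = traitY, covG = full$covG,
                 sigma2GX = full$sXX, sigma2GY = full$sYY,
                 rG = full$rG, seRG = seRG),
            class = "geneticCovariance")
}

## Genetic covariance of two trait columns by the EMS contrast on mean
## cross-products (traitX == traitY gives the untruncated genetic variance).
.covG_ems <- function(tbl, traitX, traitY) {
  x <- tbl[[traitX]]; y <- tbl[[traitY]]
  G <- factor(tbl$genotype); Y <- factor(tbl$year)
  g <- nlevels(G); e <- nlevels(Y); r <- nrow(tbl) / (g * e)
  dev <- function(z) {
    m_g <- tapply(z, G, mean); m_y <- tapply(z, Y, mean)
    m_gy <- tapply(z, list(G, Y), mean)
    list(gd = m_g - mean(z),
         gyd = sweep(sweep(m_gy, 1, m_g), 2, m_y - mean(z)))
  }
  dx <- dev(x); dy <- dev(y)
  mcp_g <- e * r * sum(dx$gd * dy$gd) / (g - 1)
  mcp_gy <- r * sum(dx$gyd * dy$gyd) / ((g - 1) * (e - 1))
  (mcp_g - mcp_gy) / (e * r)
}

#' @export
print.geneticCovariance <- function(x, ...) {
  cat(sprintf("Genetic covariance %s ~ %s: CovG = %.4g, rG = %.3f%s\n",
              x$traitX, x$traitY, x$covG, x$rG,
              if (is.finite(x$seRG)) sprintf(" +/- %.3f", x$seRG) else ""))
  invisible(x)
}

#' Plot-level Pearson correlation with significance stars
#'
#' @inheritParams geneticCovariance
#' @return list with \code{r}, \code{p}, \code{stars} (\code{""},
#'   \code{"*"}, \code{"**"}, \code{"***"} at 0.05/0.01/0.001), \code{n}.
#' @export
pearsonCor <- function(table, traitX, traitY) {
  x <- table[[traitX]]; y <- table[[traitY]]
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance; correlation undefined")
  ct <- stats::cor.test(x, y)
  stars <- if (ct$p.value < 0.001) "***" else if (ct$p.value < 0.01) "**"
    else if (ct$p.value < 0.05) "*" else ""
  list(r = unname(ct$estimate), p = ct$p.value, stars = stars,
       n = length(x))
}

#' Efficiency of indirect selection
#'
#' EI = |rG| * hX / hY, with hX the square root of the secondary-trait
#' heritability and hY the square root of the primary-trait
#' heritability, reported as a percentage of direct selection.
#'
#' @param rG genetic correlation between secondary and primary trait
#'   (absolute value is used).
#' @param H2_secondary,H2_primary heritabilities; \code{H2_primary > 0},
#'   and a negative \code{H2_secondary} (an untruncated input) is an
#'   error.
#' @return list of class \code{"selectionEfficiency"} with \code{rG}
#'   (absolute), \code{hX}, \code{hY} and \code{EI} (percent).
#' @examples
#' indirectSelectionEfficiency(0.97, 0.50, 0.64)$EI
#' @export
indirectSelectionEfficiency <- function(rG, H2_secondary, H2_primary) {
  if (!all(is.finite(c(rG, H2_secondary, H2_primary))))
    stop("inputs must be finite")
  if (H2_secondary < 0) stop("H2_secondary must be >= 0")
  if (H2_primary <= 0) stop("H2_primary must be > 0")
  hX <- sqrt(H2_secondary); hY <- sqrt(H2_primary)
  structure(list(rG = abs(rG), hX = hX, hY = hY,
                 EI = 100 * abs(rG) * hX / hY),
            class = "selectionEfficiency")
}

#' @export
print.selectionEfficiency <- function(x, ...) {
  cat(sprintf("Indirect selection efficiency: %.2f%% of direct selection\n",
              x$EI))
  invisible(x)
}

#' Fisher's least significant difference with letter grouping
#'
#' LSD = t(1 - alpha/2, df_error) * sqrt(2 MS_error / n); means whose
#' difference exceeds the LSD get different letters. Because the
#' not-significantly-different relation is an interval property on
#' sorted means under a single LSD threshold, the compact letter display
#' is the set of maximal runs of mutually compatible means.
#'
#' @param anova an [anovaTrial()] result (supplies MS_error and its df).
#' @param means named vector of group means.
#' @param n_per_mean observations per mean (> 0).
#' @param level significance level (default 0.05).
#' @return list with \code{lsd} and \code{groups} (data.frame of mean,
#'   letters, sorted decreasing).
#' @export
fisherLSD <- function(anova, means, n_per_mean, level = 0.05) {
  if (n_per_mean <= 0) stop("n_per_mean must be positive")
  err <- anova[anova$source == "Error", ]
  lsd <- stats::qt(1 - level / 2, err$df) * sqrt(2 * err$ms / n_per_mean)
  o <- order(means, decreasing = TRUE)
  m <- means[o]
  k <- length(m)
  ## maximal intervals [i..j] with m[i] - m[j] <= lsd
  runs <- list()
  i <- 1L
  while (i <= k) {
    j <- i
    while (j < k && m[i] - m[j + 1L] <= lsd) j <- j + 1L
    runs[[length(runs) + 1L]] <- i:j
    ## next run starts at the first index not covered by this one
    nxt <- j + 1L
    if (nxt > k) break
    i2 <- nxt
    while (i2 > i + 1L && m[i2 - 1L] - m[nxt] <= lsd) i2 <- i2 - 1L
    i <- i2
  }
  ## drop runs fully contained in another
  keep <- vapply(seq_along(runs), function(a)
    !any(vapply(seq_along(runs), function(b)
      b != a && all(runs[[a]] %in% runs[[b]]), logical(1))), logical(1))
  runs <- runs[keep]
  letters_out <- character(k)
  for (ri in seq_along(runs))
    letters_out[runs[[ri]]] <- paste0(letters_out[runs[[ri]]],
                                      letters[ri])
  list(lsd = lsd,
       groups = data.frame(mean = m, letters = letters_out,
                           row.names = names(m)))
}

#' Standard error of a mean
#'
#' Sample standard deviation divided by the square root of the sample
#' size.
#'
#' @param values numeric vector, length >= 2.
#' @return numeric SE.
#' @export
standardError <- function(values) {
  n <- length(values)
  if (n < 2L) stop("need at least 2 values")
  stats::sd(values) / sqrt(n)
}
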