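test_that("grain-yield standardisation matches the hand formula", {
  # 10 kg at exactly 14 % moisture on 7 m2: 10 * 10^4/7 / 1000 t/ha
  expect_equal(gyStandardize(10, 14, plot_area = 7), 100 / 7)
  # moisture above 14 % shrinks dry matter proportionally
  expect_equal(gyStandardize(10, 21.5, plot_area = 7),
               (10 * (100 - 21.5) / 86 * 1e4 / 7) / 1000)
  expect_error(gyStandardize(10, 120), "moisture")
})

test_that("trial table assembly merges fluorescence traits", {
  trial <- small_trial(seed = 21L, n_timepoints = 30L)
  jp <- jipTable(trial$transients, "plot")
  tbl <- trialTable(trial$agro, jp)
  expect_true(all(c("genotype", "year", "rep", "block", "gy", "gm",
                    "fvfm", "piabs") %in% names(tbl)))
  expect_equal(nrow(tbl), nrow(trial$agro))
  expect_equal(sort(tbl$gy), sort(trial$agro$gy_t_ha))
  # fvfm column is the plot phi_Po
  row <- tbl[tbl$genotype == "H01" & tbl$year == 2017 & tbl$rep == 1, ]
  src <- jp[jp$genotype == "H01" & jp$year == 2017 & jp$rep == 1, ]
  expect_equal(row$fvfm, src$phi_Po)
  expect_error(trialTable(trial$agro[, -4]), "missing columns")
})

test_that("ANOVA degrees of freedom and additivity hold", {
  tab <- balanced_table(g = 8L, e = 3L, r = 4L, seed = 2L)
  an <- anovaTrial(tab, "y")
  expect_equal(an$df, c(7, 2, 9, 9, 14, 54))
  expect_equal(sum(an$df), nrow(tab) - 1)
  expect_equal(sum(an$ss), sum((tab$y - mean(tab$y))^2), tolerance = 1e-9)
  expect_true(all(an$ss > -1e-9))
  expect_equal(an$F[1], an$ms[1] / an$ms[6])
})

test_that("ANOVA strata agree with aov on the orthogonal layout", {
  tab <- balanced_table(g = 8L, e = 3L, r = 4L, seed = 3L)
  an <- anovaTrial(tab, "y")
  d <- data.frame(y = tab$y, G = factor(tab$genotype),
                  Y = factor(tab$year), R = factor(tab$rep),
                  B = factor(tab$block))
  ref <- summary(stats::aov(y ~ Y + Y:R + Y:B + G + G:Y, data = d))[[1]]
  ss <- setNames(ref[["Sum Sq"]], trimws(rownames(ref)))
  expect_equal(an$ss[an$source == "Genotype"], ss[["G"]],
               tolerance = 1e-8)
  expect_equal(an$ss[an$source == "Year"], ss[["Y"]], tolerance = 1e-8)
  expect_equal(an$ss[an$source == "Replication(Year)"], ss[["Y:R"]],
               tolerance = 1e-8)
  expect_equal(an$ss[an$source == "Block(Year)"], ss[["Y:B"]],
               tolerance = 1e-8)
  expect_equal(an$ss[an$source == "Genotype:Year"], ss[["Y:G"]],
               tolerance = 1e-8)
  expect_equal(an$ss[an$source == "Error"], ss[["Residuals"]],
               tolerance = 1e-8)
})

test_that("ANOVA rejects unbalanced or broken input", {
  tab <- balanced_table(g = 4L, e = 2L, r = 2L)
  expect_error(anovaTrial(tab[-1, ], "y"), "not balanced")
  expect_error(anovaTrial(tab, "nope"), "not found")
  tab$y[1] <- NA
  expect_error(anovaTrial(tab, "y"), "finite")
})

test_that("variance components match a fully hand-computed oracle", {
  # additive 2x2x2 layout; every SS worked out on paper:
  # SS_G = 242, SS_Y = 50, SS_Rep(Y) = 8, SS_GxY = 2, SS_E = 0
  tab <- data.frame(
    genotype = rep(c("A", "B"), each = 4),
    year = rep(rep(1:2, each = 2), 2),
    rep = rep(1:2, 4), block = 1L,
    y = c(10, 12, 14, 16, 20, 22, 26, 28))
  an <- anovaTrial(tab, "y")
  expect_equal(an$ss, c(242, 50, 8, 0, 2, 0), tolerance = 1e-10)
  vc <- estimateVarianceComponents(tab, "y", jackknife = FALSE)
  # sigma2_e = MS_E = 0; sigma2_GxE = (2 - 0)/2 = 1
  # sigma2_G = (242 - 2)/4 = 60; sigma2_E = (50 - 4)/4 = 11.5
  expect_equal(vc@sigma2e, 0)
  expect_equal(vc@sigma2GxE, 1)
  expect_equal(vc@sigma2G, 60)
  expect_equal(vc@sigma2E, 11.5)
  expect_equal(heritability(vc), 60 / (60 + 1 / 2 + 0), tolerance = 1e-12)
})

test_that("EMS estimates agree with REML on balanced data", {
  tab <- balanced_table(g = 12L, e = 3L, r = 4L, sd_g = 1.2,
                        sd_gxe = 0.6, sd_rep = 0.3, sd_e = 0.8,
                        seed = 7L)
  vc <- estimateVarianceComponents(tab, "y", jackknife = FALSE)
  fit <- lme4::lmer(
    y ~ factor(year) + factor(year):factor(rep) +
      factor(year):factor(block) + (1 | genotype) + (1 | genotype:year),
    data = tab, REML = TRUE)
  vv <- as.data.frame(lme4::VarCorr(fit))
  s2 <- setNames(vv$vcov, vv$grp)
  expect_equal(vc@sigma2G, unname(s2[["genotype"]]), tolerance = 1e-4)
  expect_equal(vc@sigma2GxE, unname(s2[["genotype:year"]]),
               tolerance = 1e-4)
  expect_equal(vc@sigma2e, unname(s2[["Residual"]]), tolerance = 1e-4)
})

test_that("negative EMS solutions are truncated at zero", {
  # no genotype signal at all: sampling noise makes raw sigma2_G / GxE
  # negative about half the time; estimates must never go below 0
  for (s in 1:6) {
    tab <- balanced_table(g = 6L, e = 2L, r = 2L, sd_g = 0, sd_gxe = 0,
                          sd_rep = 0, sd_e = 1, seed = s)
    vc <- estimateVarianceComponents(tab, "y", jackknife = FALSE)
    expect_gte(vc@sigma2G, 0)
    expect_gte(vc@sigma2GxE, 0)
  }
})

test_that("heritability reproduces the worked moisture example", {
  vc <- varianceComponents(1.296, 2.209, 0.795, nE = 3, nR = 4,
                           trait = "gm")
  expect_equal(round(heritability(vc), 4), 0.6176)
  expect_warning(h0 <- heritability(varianceComponents(0, 0, 0)),
                 "undefined")
  expect_true(is.na(h0))
})

test_that("jackknife SE of heritability behaves", {
  tab <- balanced_table(g = 10L, e = 3L, r = 3L, seed = 5L)
  vc <- estimateVarianceComponents(tab, "y", jackknife = TRUE)
  expect_true(is.finite(vc@seH2) && vc@seH2 > 0)
  expect_lt(vc@seH2, 0.5)
  vc0 <- estimateVarianceComponents(tab, "y", jackknife = FALSE)
  expect_true(is.na(vc0@seH2))
  expect_equal(vc@sigma2G, vc0@sigma2G)
})

test_that("genetic covariance recovers an additive construction exactly", {
  tab <- balanced_table(g = 10L, e = 3L, r = 4L, seed = 9L)
  set.seed(10)
  noise <- rnorm(nrow(tab))
  # centre the noise within genotype-by-year cells so it cannot move the
  # genotype or interaction strata: then CovG(x, y) = sigma2_G(x), rG = 1
  cell <- interaction(tab$genotype, tab$year)
  tab$x <- tab$y
  tab$y2 <- tab$y + noise - ave(noise, cell)
  gc <- geneticCovariance(tab, "x", "y2", jackknife = FALSE)
  expect_equal(gc$rG, 1, tolerance = 1e-10)
  expect_equal(gc$covG, gc$sigma2GX, tolerance = 1e-10)
  expect_equal(gc$sigma2GY, gc$sigma2GX, tolerance = 1e-10)

  # sign flip: rG(x, -y) = -rG(x, y)
  tab$y3 <- -tab$y2
  expect_equal(geneticCovariance(tab, "x", "y3", jackknife = FALSE)$rG,
               -1, tolerance = 1e-10)

  # jackknife SE exists and is small for this near-deterministic case
  gcj <- geneticCovariance(tab, "x", "y2")
  expect_true(is.finite(gcj$seRG))
  expect_lt(gcj$seRG, 0.05)
})

test_that("genetic correlation degeneracies are flagged, never clipped", {
  tab <- balanced_table(g = 6L, e = 2L, r = 2L, sd_g = 0, sd_gxe = 0,
                        sd_e = 1, seed = 4L)
  set.seed(2)
  tab$x <- rnorm(nrow(tab))
  res <- withCallingHandlers(
    geneticCovariance(tab, "x", "y", jackknife = FALSE),
    warning = function(w) invokeRestart("muffleWarning"))
  expect_true(is.na(res$rG) || abs(res$rG) >= 0)  # defined or NA, no error
  expect_error(geneticCovariance(tab[-1, ], "x", "y"), "not balanced")
})

test_that("Pearson correlation reports r, p and stars", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  res <- pearsonCor(data.frame(a = x, b = 2 * x + c(0.1, -0.1, 0.05,
                                                    -0.05, 0.1, -0.1,
                                                    0.05, -0.05)),
                    "a", "b")
  expect_gt(res$r, 0.99)
  expect_equal(res$stars, "***")
  expect_equal(res$n, 8L)
  expect_error(pearsonCor(data.frame(a = x, b = rep(1, 8)), "a", "b"),
               "zero variance")
})

test_that("indirect selection efficiency satisfies its identities", {
  # equal heritabilities and perfect correlation: EI = 100 %
  expect_equal(indirectSelectionEfficiency(1, 0.5, 0.5)$EI, 100)
  # sign of rG is irrelevant
  expect_equal(indirectSelectionEfficiency(-0.8, 0.4, 0.6)$EI,
               indirectSelectionEfficiency(0.8, 0.4, 0.6)$EI)
  # EI scales as sqrt(H2_secondary) at fixed rG and primary H2
  e1 <- indirectSelectionEfficiency(0.5, 0.36, 0.5)$EI
  e2 <- indirectSelectionEfficiency(0.5, 0.09, 0.5)$EI
  expect_equal(e1 / e2, 2)
  # worked example: EI = 100 * 0.97 * sqrt(0.50 / 0.64) = 85.74 %
  expect_equal(round(indirectSelectionEfficiency(0.97, 0.50, 0.64)$EI, 2),
               85.74)
  expect_error(indirectSelectionEfficiency(0.5, -0.1, 0.5), ">= 0")
  expect_error(indirectSelectionEfficiency(0.5, 0.5, 0), "> 0")
})

test_that("Fisher LSD value and letter grouping are correct", {
  fake <- data.frame(source = c("Genotype", "Error"), df = c(3, 12),
                     ss = c(9, 6), ms = c(3, 0.5), F = NA, p = NA)
  res <- fisherLSD(fake, c(a = 10, b = 9.9, c = 5), n_per_mean = 4)
  expect_equal(res$lsd, qt(0.975, 12) * sqrt(2 * 0.5 / 4))
  expect_equal(res$groups["a", "letters"], res$groups["b", "letters"])
  expect_false(res$groups["c", "letters"] ==
                 res$groups["a", "letters"])

  # chained overlap: A ~ B, B ~ C, but A != C  ->  a / ab / b
  fake2 <- data.frame(source = "Error", df = 10, ss = 0.9, ms = 0.09,
                      F = NA, p = NA)
  res2 <- fisherLSD(fake2, c(A = 10, B = 9.5, C = 9.0), n_per_mean = 2)
  expect_true(res2$lsd > 0.5 && res2$lsd < 1.0)
  expect_equal(res2$groups$letters, c("a", "ab", "b"))
  expect_error(fisherLSD(fake2, c(A = 1, B = 2), n_per_mean = 0),
               "positive")
})

test_that("standard error of a mean", {
  expect_equal(standardError(c(0, 2)), 1)
  expect_equal(standardError(1:4), sd(1:4) / 2)
  expect_error(standardError(5), "at least 2")
})

test_that("reference variance components give the published heritabilities", {
  ref <- referenceVarianceComponents()
  h2 <- vapply(seq_len(nrow(ref)), function(i)
    heritability(varianceComponents(ref$sigma2_G[i], ref$sigma2_GxE[i],
                                    ref$sigma2_e[i], nE = ref$nE[i],
                                    nR = ref$nR[i])), numeric(1))
  names(h2) <- ref$trait
  expect_equal(round(h2[["gm"]], 2), 0.62)
  expect_equal(round(h2[["piabs"]], 2), 0.84)
  expect_equal(round(h2[["gy_parameters"]], 2), 0.65)
  expect_equal(round(h2[["gm_parameters"]], 2), 0.32)
  expect_equal(round(h2[["gy_transients"]], 2), 0.50)
})
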