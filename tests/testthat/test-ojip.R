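test_that("landmark extraction matches closed-form curves", {
  tt <- ojipTimeGrid()

  # flat curve: every landmark equals the constant, area is zero
  lm_flat <- extractLandmarks(tt, rep(700, length(tt)))
  expect_true(all(unlist(lm_flat[c("F0", "F1", "F2", "F3", "F4", "F5",
                                   "Fm")]) == 700))
  expect_equal(lm_flat$area, 0)

  # single-exponential rise evaluated in closed form
  f <- 200 + 800 * (1 - exp(-tt / 0.03))
  lm <- extractLandmarks(tt, f)
  expect_equal(lm$Fm, 200 + 800 * (1 - exp(-tt[length(tt)] / 0.03)))
  expect_equal(lm$t_Fm, tt[length(tt)])
  expect_equal(lm$F5, 200 + 800 * (1 - exp(-1)))   # exact 30 ms grid point
  expect_equal(lm$F4, 200 + 800 * (1 - exp(-2e-3 / 0.03)))

  # grid that misses the early markers names the missing landmark
  late <- tt[tt > 1e-3]
  expect_error(extractLandmarks(late, seq_along(late) + 100), "F1")
})

test_that("monotone transients give ordered landmarks and V in [0, 1]", {
  trial <- small_trial(seed = 3L, n_timepoints = 118L)
  vals <- fluorValues(trial$transients)
  tt <- fluorTimes(trial$transients)
  expect_true(all(apply(vals, 2, function(v) all(diff(v) >= 0))))
  for (j in c(1L, ncol(vals))) {
    lm <- extractLandmarks(tt, vals[, j])
    expect_true(all(diff(unlist(lm[c("F0", "F1", "F2", "F3", "F4",
                                     "F5", "Fm")])) >= 0))
    p <- computeJIP(lm)
    expect_true(p[["VJ"]] >= 0 && p[["VJ"]] <= p[["VI"]] &&
                  p[["VI"]] <= 1)
  }
})

test_that("normalization maps F0 to 0 and Fm to 1", {
  tt <- ojipTimeGrid()
  f <- test_curve(tt)
  lm <- extractLandmarks(tt, f)
  nv <- normalizeTransient(tt, f, lm)
  i0 <- which.min(abs(tt - 50e-6))
  expect_equal(nv$V[i0], 0)
  expect_equal(max(nv$V), 1)
  # hand value: F0 = 500, Fm = 2500, F(2 ms) = 1700 -> VJ = 0.6
  expect_equal((1700 - 500) / (2500 - 500), 0.6)
  expect_error(normalizeTransient(tt, rep(5, length(tt)),
                                  list(F0 = 5, Fm = 5)),
               "degenerate")
})

test_that("JIP parameters reproduce hand-computed values", {
  # phi_Po from F0 = 500, Fm = 2500
  p <- computeJIP(list(F0 = 500, F1 = 500, F2 = 700, F3 = 900,
                       F4 = 1700, F5 = 2100, Fm = 2500, t_Fm = 0.3,
                       area = 100))
  expect_equal(p[["phi_Po"]], 0.8)
  # M0 = 4 * 400 / 2000 = 0.8 /ms; VJ = 0.6; RC/ABS = 0.8*0.6/0.8 = 0.6
  expect_equal(p[["M0"]], 0.8)
  expect_equal(p[["VJ"]], 0.6)
  expect_equal(p[["RC_ABS"]], 0.6)
  # dVG/dt0 = (700 - 500)/((2500 - 500) * 0.05 ms) = 2 /ms
  expect_equal(p[["dVG_dt0"]], 2)

  # identity point of the performance-index product:
  # phi_Po = 0.5, psi_Eo = 0.5, RC/ABS = 1  =>  PI_ABS = 1
  lm1 <- landmarks_from(phi_Po = 0.5, VJ = 0.5, M0 = 0.25)
  p1 <- computeJIP(lm1)
  expect_equal(p1[["psi_Eo"]], 0.5)
  expect_equal(p1[["RC_ABS"]], 1)
  expect_equal(p1[["PI_ABS"]], 1)
})

test_that("ratio parameters are invariant to overall fluorescence scale", {
  lm <- extractLandmarks(ojipTimeGrid(), test_curve())
  p1 <- computeJIP(lm)
  lm2 <- lm
  for (nm in c("F0", "F1", "F2", "F3", "F4", "F5", "Fm"))
    lm2[[nm]] <- lm2[[nm]] * 3.7
  lm2$area <- lm2$area * 3.7
  p2 <- computeJIP(lm2)
  dimless <- c("VJ", "VI", "VK", "M0", "dVG_dt0", "Sm", "N",
               "phi_Po", "psi_Eo", "phi_Eo", "delta_Ro", "phi_Ro",
               "gamma_RC", "RC_ABS", "ABS_RC", "TR0_RC", "ET0_RC",
               "RE0_RC", "PI_ABS", "PI_total", "SFI_ABS")
  expect_equal(p1[dimless], p2[dimless], tolerance = 1e-12)
})

test_that("PI_ABS responds monotonically to its three factors", {
  # increasing phi_Po at fixed VJ, M0 (both PI factors rise)
  pis <- vapply(seq(0.3, 0.9, by = 0.1), function(phi)
    computeJIP(landmarks_from(phi, VJ = 0.5, M0 = 0.8))[["PI_ABS"]],
    numeric(1))
  expect_true(all(diff(pis) > 0))
  # increasing psi_Eo = 1 - VJ at fixed phi_Po, M0
  pis <- vapply(seq(0.7, 0.2, by = -0.1), function(vj)
    computeJIP(landmarks_from(0.8, VJ = vj, M0 = 0.8))[["PI_ABS"]],
    numeric(1))
  expect_true(all(diff(pis) > 0))
  # increasing RC/ABS via decreasing M0 at fixed phi_Po, VJ
  pis <- vapply(seq(1.2, 0.4, by = -0.2), function(m0)
    computeJIP(landmarks_from(0.8, VJ = 0.5, M0 = m0))[["PI_ABS"]],
    numeric(1))
  expect_true(all(diff(pis) > 0))
})

test_that("undefined ratios are flagged, not infinite", {
  # VJ = 1 (F4 = Fm) makes delta_Ro and PI_ABS undefined
  p <- computeJIP(list(F0 = 500, F1 = 500, F2 = 600, F3 = 900,
                       F4 = 2500, F5 = 2500, Fm = 2500, t_Fm = 0.5,
                       area = 100))
  expect_true(is.na(p[["delta_Ro"]]))
  expect_true(is.na(p[["PI_ABS"]]))
  expect_true(all(c("delta_Ro", "PI_ABS") %in%
                    names(attr(p, "undefined"))))
  expect_false(any(is.infinite(p), na.rm = TRUE))
})

test_that("jipTable vectorizes, averages plots, and handles edge cases", {
  expect_length(jipParameterNames("jip56"), 56L)
  expect_length(jipParameterNames("full58"), 58L)

  tt <- ojipTimeGrid(60)
  f <- test_curve(tt)
  keys <- data.frame(genotype = "H1", year = 2017L, rep = 1L,
                     plant = 1:3)
  x <- fluorTransientSet(tt, cbind(f, f, f), keys)
  plant <- jipTable(x, "plant")
  plot <- jipTable(x, "plot")
  expect_equal(nrow(plant), 3L)
  expect_equal(nrow(plot), 1L)
  # identical plants: plot mean equals the plant value
  expect_equal(plot$PI_ABS, plant$PI_ABS[1])

  # missing plant: mean over available plants, with a warning
  x2 <- fluorTransientSet(tt, cbind(f, f, f, f * 1.1, f * 1.1),
                          data.frame(genotype = c("H1", "H1", "H1",
                                                  "H2", "H2"),
                                     year = 2017L, rep = 1L,
                                     plant = c(1:3, 1:2)))
  expect_warning(plot2 <- jipTable(x2, "plot"), "unequal plant counts")
  expect_equal(nrow(plot2), 2L)

  # empty input: empty table, no error
  x0 <- fluorTransientSet(tt, matrix(numeric(0), length(tt), 0),
                          data.frame(genotype = character(),
                                     year = integer(), rep = integer(),
                                     plant = integer()))
  expect_equal(nrow(jipTable(x0, "plant")), 0L)
})

test_that("transient CSV writer and reader round-trip", {
  trial <- small_trial(seed = 5L, n_timepoints = 30L)
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp), add = TRUE)
  writeTransientsCSV(trial$transients, tmp)
  back <- readTransientsCSV(tmp)
  # times serialize at 6 significant digits (t_<microseconds> headers)
  expect_equal(fluorTimes(back), fluorTimes(trial$transients),
               tolerance = 1e-5)
  expect_equal(unname(fluorValues(back)),
               unname(fluorValues(trial$transients)), tolerance = 1e-9)
  expect_equal(sampleKeys(back)$genotype,
               sampleKeys(trial$transients)$genotype)
})
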