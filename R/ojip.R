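## OJIP landmark times (seconds) as sampled by plant-efficiency analysers:
## O at 50 us (F1), 100 us (F2), 300 us (F3), J at 2 ms (F4), I at 30 ms (F5).
.ojip_marker_times <- c(F1 = 50e-6, F2 = 100e-6, F3 = 300e-6,
                        F4 = 2e-3, F5 = 30e-3)

#' Quasi-logarithmic OJIP acquisition time grid
#'
#' Builds the default acquisition grid of a fast-fluorescence induction
#' measurement: \code{n} points log-spaced between \code{t_min} and
#' \code{t_max}, with the grid points nearest to the instrument marker
#' times (50 us, 100 us, 300 us, 2 ms, 30 ms) snapped exactly onto them,
#' as instrument exports sample exactly at the marker signals.
#'
#' @param n number of timepoints (default 118).
#' @param t_min,t_max grid limits in seconds (defaults 20 us and 1 s).
#' @return strictly increasing numeric vector of times in seconds.
#' @export
ojipTimeGrid <- function(n = 118L, t_min = 2e-5, t_max = 1) {
  stopifnot(n >= 2L, t_min > 0, t_max > t_min)
  tt <- 10^seq(log10(t_min), log10(t_max), length.out = n)
  for (m in .ojip_marker_times) {
    if (m >= t_min && m <= t_max) {
      i <- which.min(abs(log(tt) - log(m)))
      tt[i] <- m
    }
  }
  stopifnot(all(diff(tt) > 0))
  tt
}

.nearest_index <- function(times, target) which.min(abs(times - target))

#' Extract OJIP landmarks from one fluorescence transient
#'
#' Locates the classical induction-curve landmarks: the zero-level
#' fluorescence F0 (reading at the 50 us marker, the standard O point of
#' hand-held fluorometers), the marker signals F1..F5 at 50 us, 100 us,
#' 300 us, 2 ms (J step) and 30 ms (I step), the maximum fluorescence Fm
#' (P step, first occurrence) with its time, and the complementary area
#' between the curve and the horizontal line F = Fm from the F0 time to
#' the time of Fm (trapezoidal rule).
#'
#' Landmark lookup uses the nearest grid point, with a tolerance of one
#' grid step; a grid not covering a marker time raises an error naming
#' the missing landmark.
#'
#' @param times numeric vector of acquisition times (seconds), strictly
#'   increasing.
#' @param values numeric vector of positive fluorescence readings, same
#'   length.
#' @return a named list of class \code{"ojipLandmarks"} with elements
#'   \code{F0, F1, F2, F3, F4, F5, Fm, t_Fm, area}.
#' @examples
#' tt <- ojipTimeGrid()
#' f  <- 200 + 800 * (1 - exp(-tt / 0.03))
#' extractLandmarks(tt, f)
#' @export
extractLandmarks <- function(times, values) {
  stopifnot(length(times) == length(values), all(diff(times) > 0))
  if (any(!is.finite(values)) || any(values <= 0))
    stop("fluorescence values must be finite and positive")
  lm <- vapply(names(.ojip_marker_times), function(nm) {
    m <- .ojip_marker_times[[nm]]
    i <- .nearest_index(times, m)
    step <- if (i < length(times)) times[i + 1L] - times[i] else
      times[i] - times[i - 1L]
    if (abs(times[i] - m) > step)
      stop("time grid does not cover landmark ", nm, " (",
           format(m), " s)")
    values[i]
  }, numeric(1))
  i_fm <- which.max(values)
  i_f0 <- .nearest_index(times, .ojip_marker_times[["F1"]])
  idx <- seq(i_f0, max(i_fm, i_f0))
  area <- if (length(idx) > 1) {
    dy <- values[i_fm] - values[idx]
    sum(diff(times[idx]) * (head(dy, -1) + dy[-1]) / 2)
  } else 0
  structure(list(F0 = unname(lm[["F1"]]), F1 = unname(lm[["F1"]]),
                 F2 = unname(lm[["F2"]]), F3 = unname(lm[["F3"]]),
                 F4 = unname(lm[["F4"]]), F5 = unname(lm[["F5"]]),
                 Fm = unname(values[i_fm]), t_Fm = unname(times[i_fm]),
                 area = area),
            class = "ojipLandmarks")
}

#' Normalize a transient to relative variable fluorescence
#'
#' Rescales a raw induction curve with total variable fluorescence:
#' V(t) = (F(t) - F0) / (Fm - F0), so V = 0 at the zero-level landmark
#' and V = 1 at the maximum.
#'
#' @param times,values one transient as in [extractLandmarks()].
#' @param landmarks optional precomputed [extractLandmarks()] result.
#' @return list with \code{times} and \code{V} (dimensionless).
#' @export
normalizeTransient <- function(times, values, landmarks = NULL) {
  if (is.null(landmarks)) landmarks <- extractLandmarks(times, values)
  if (landmarks$Fm <= landmarks$F0) stop("degenerate transient: Fm <= F0")
  list(times = times, V = (values - landmarks$F0) / (landmarks$Fm - landmarks$F0))
}

#' Canonical JIP-test parameter roster
#'
#' Ordered names of the derived biophysical parameter set. The full
#' roster has 58 entries: the 56 JIP-test quantities (landmark signals,
#' relative variable fluorescence, slopes, area-derived turnover
#' quantities, quantum yields and probabilities, specific and
#' cross-section energy fluxes, performance indices and driving forces)
#' plus the raw F0 and Fm signals. Preset \code{"jip56"} drops the two
#' raw signals.
#'
#' @param preset \code{"full58"} (default) or \code{"jip56"}.
#' @return character vector of parameter names, in fixed column order.
#' @export
jipParameterNames <- function(preset = c("full58", "jip56")) {
  preset <- match.arg(preset)
  core56 <- c(
    "F1", "F2", "F3", "F4", "F5", "t_Fm", "Area", "Fv",
    "Fv_F0", "F0_Fm", "VJ", "VI", "VK", "M0", "dVG_dt0",
    "Sm", "Ss", "N",
    "phi_Po", "phi_Do", "psi_Eo", "phi_Eo", "delta_Ro", "phi_Ro", "psi_Ro",
    "gamma_RC", "RC_ABS", "ABS_RC", "TR0_RC", "ET0_RC", "RE0_RC", "DI0_RC",
    "ABS_CS0", "TR0_CS0", "ET0_CS0", "RE0_CS0", "DI0_CS0", "RC_CS0",
    "ABS_CSm", "TR0_CSm", "ET0_CSm", "RE0_CSm", "DI0_CSm", "RC_CSm",
    "PI_ABS", "PI_total", "PI_CS0", "PI_CSm",
    "SFI_ABS", "DF_ABS", "DF_total",
    "phi_Pav", "Sm_tFm", "FJ_F0", "FI_F0", "Fm_F0")
  if (preset == "jip56") core56 else c(core56, "F0", "Fm")
}

#' Compute the JIP-test biophysical parameters from OJIP landmarks
#'
#' Applies the energy-flux framework of the JIP-test to one landmark
#' set. Key definitions (V denotes relative variable fluorescence):
#' \itemize{
#'   \item VJ = (F4 - F0)/(Fm - F0), VI = (F5 - F0)/(Fm - F0)
#'   \item M0 = 4/ms * (F3 - F1)/(Fm - F1), the initial slope of V(t)
#'   \item dVG/dt0 = (F2 - F1)/((Fm - F1) * 0.05 ms), the early
#'     curve inclination
#'   \item phi_Po = 1 - F0/Fm (= Fv/Fm), psi_Eo = 1 - VJ,
#'     phi_Eo = phi_Po * psi_Eo, delta_Ro = (1 - VI)/(1 - VJ),
#'     phi_Ro = phi_Eo * delta_Ro
#'   \item RC/ABS = gamma_RC/(1 - gamma_RC) = phi_Po * VJ / M0
#'   \item specific fluxes per reaction centre: TR0/RC = M0/VJ,
#'     ABS/RC = TR0/RC / phi_Po, ET0/RC = TR0/RC * psi_Eo,
#'     RE0/RC = ET0/RC * delta_Ro, DI0/RC = ABS/RC - TR0/RC
#'   \item cross-section fluxes: ABS/CS0 approximated by F0 and
#'     ABS/CSm by Fm, each multiplied by the corresponding yields
#'   \item Sm = Area/(Fm - F0), Ss = VJ/M0, N = Sm * M0 / VJ
#'   \item PI_ABS = (RC/ABS) * phi_Po/(1 - phi_Po) * psi_Eo/(1 - psi_Eo);
#'     PI_total = PI_ABS * delta_Ro/(1 - delta_Ro)
#' }
#' Ratios whose denominator vanishes (e.g. VJ or phi_Po at 0 or 1) are
#' returned as \code{NA} and listed, with a reason, in the
#' \code{"undefined"} attribute rather than propagating infinities.
#'
#' @param landmarks an [extractLandmarks()] result (or compatible list).
#' @param preset parameter roster, see [jipParameterNames()].
#' @return named numeric vector in roster order, with attribute
#'   \code{"undefined"} naming flagged parameters (empty when none).
#' @examples
#' p <- computeJIP(list(F0 = 500, F1 = 500, F2 = 700, F3 = 900,
#'                      F4 = 1700, F5 = 2100, Fm = 2500, t_Fm = 0.3,
#'                      area = 100))
#' p[["phi_Po"]]  # 0.8
#' @export
computeJIP <- function(landmarks, preset = c("full58", "jip56")) {
  preset <- match.arg(preset)
  l <- landmarks
  if (!(l$Fm > l$F0 && l$F0 > 0)) stop("require Fm > F0 > 0")
  undef <- character()
  flag <- function(nm, why) undef <<- c(undef, setNames(why, nm))
  Fv <- l$Fm - l$F0
  VJ <- (l$F4 - l$F0) / Fv
  VI <- (l$F5 - l$F0) / Fv
  VK <- (l$F3 - l$F0) / Fv
  M0 <- 4 * (l$F3 - l$F1) / (l$Fm - l$F1)        # per ms
  dVG <- (l$F2 - l$F1) / ((l$Fm - l$F1) * 0.05)  # per ms
  phi_Po <- 1 - l$F0 / l$Fm
  phi_Do <- 1 - phi_Po
  psi_Eo <- 1 - VJ
  phi_Eo <- phi_Po * psi_Eo
  delta_Ro <- if (abs(1 - VJ) < 1e-12) {
    flag("delta_Ro", "VJ = 1"); NA_real_
  } else (1 - VI) / (1 - VJ)
  phi_Ro <- phi_Eo * delta_Ro
  psi_Ro <- psi_Eo * delta_Ro
  RC_ABS <- if (abs(M0) < 1e-12) {
    flag("RC_ABS", "M0 = 0"); NA_real_
  } else phi_Po * VJ / M0
  gamma_RC <- RC_ABS / (1 + RC_ABS)
  TR0_RC <- if (abs(VJ) < 1e-12) {
    flag("TR0_RC", "VJ = 0"); NA_real_
  } else M0 / VJ
  ABS_RC <- if (phi_Po < 1e-12) {
    flag("ABS_RC", "phi_Po = 0"); NA_real_
  } else TR0_RC / phi_Po
  ET0_RC <- TR0_RC * psi_Eo
  RE0_RC <- ET0_RC * delta_Ro
  DI0_RC <- ABS_RC - TR0_RC
  Sm <- l$area / Fv
  Ss <- if (abs(M0) < 1e-12) NA_real_ else VJ / M0
  N  <- if (abs(VJ) < 1e-12) NA_real_ else Sm * M0 / VJ
  PI_ABS <- if (is.na(RC_ABS) || phi_Po >= 1 - 1e-12 ||
                psi_Eo >= 1 - 1e-12 || phi_Po < 1e-12 || psi_Eo < 1e-12) {
    flag("PI_ABS", "yield at 0 or 1"); NA_real_
  } else RC_ABS * phi_Po / (1 - phi_Po) * psi_Eo / (1 - psi_Eo)
  PI_total <- if (is.na(delta_Ro) || is.na(PI_ABS) ||
                  abs(1 - delta_Ro) < 1e-12) {
    flag("PI_total", "delta_Ro = 1"); NA_real_
  } else PI_ABS * delta_Ro / (1 - delta_Ro)
  out <- c(
    F1 = l$F1, F2 = l$F2, F3 = l$F3, F4 = l$F4, F5 = l$F5,
    t_Fm = l$t_Fm, Area = l$area, Fv = Fv,
    Fv_F0 = Fv / l$F0, F0_Fm = l$F0 / l$Fm,
    VJ = VJ, VI = VI, VK = VK, M0 = M0, dVG_dt0 = dVG,
    Sm = Sm, Ss = Ss, N = N,
    phi_Po = phi_Po, phi_Do = phi_Do, psi_Eo = psi_Eo, phi_Eo = phi_Eo,
    delta_Ro = delta_Ro, phi_Ro = phi_Ro, psi_Ro = psi_Ro,
    gamma_RC = gamma_RC, RC_ABS = RC_ABS, ABS_RC = ABS_RC,
    TR0_RC = TR0_RC, ET0_RC = ET0_RC, RE0_RC = RE0_RC, DI0_RC = DI0_RC,
    ABS_CS0 = l$F0, TR0_CS0 = phi_Po * l$F0, ET0_CS0 = phi_Eo * l$F0,
    RE0_CS0 = phi_Ro * l$F0, DI0_CS0 = (1 - phi_Po) * l$F0,
    RC_CS0 = RC_ABS * l$F0,
    ABS_CSm = l$Fm, TR0_CSm = phi_Po * l$Fm, ET0_CSm = phi_Eo * l$Fm,
    RE0_CSm = phi_Ro * l$Fm, DI0_CSm = (1 - phi_Po) * l$Fm,
    RC_CSm = RC_ABS * l$Fm,
    PI_ABS = PI_ABS, PI_total = PI_total,
    PI_CS0 = PI_ABS * l$F0, PI_CSm = PI_ABS * l$Fm,
    SFI_ABS = RC_ABS * phi_Po * psi_Eo,
    DF_ABS = if (is.na(PI_ABS) || PI_ABS <= 0) NA_real_ else log10(PI_ABS),
    DF_total = if (is.na(PI_total) || PI_total <= 0) NA_real_
               else log10(PI_total),
    phi_Pav = phi_Po * Sm / (l$t_Fm * 1e3),
    Sm_tFm = Sm / (l$t_Fm * 1e3),
    FJ_F0 = l$F4 / l$F0, FI_F0 = l$F5 / l$F0, Fm_F0 = l$Fm / l$F0,
    F0 = l$F0, Fm = l$Fm)
  out <- out[jipParameterNames(preset)]
  attr(out, "undefined") <- undef[names(undef) %in% names(out)]
  out
}

#' Tabulate JIP-test parameters over a transient set
#'
#' Vectorises [extractLandmarks()] + [computeJIP()] over every plant of
#' a \linkS4class{FluorTransientSet} and, at \code{level = "plot"},
#' averages the plants of each genotype-by-year-by-rep plot. A plot with
#' missing plants is averaged over the available ones with a warning.
#'
#' @param x a \linkS4class{FluorTransientSet}.
#' @param level \code{"plant"} (one row per measurement) or
#'   \code{"plot"} (one row per genotype/year/rep).
#' @param preset parameter roster, see [jipParameterNames()].
#' @return data.frame of key columns followed by the parameter columns
#'   in roster order; zero-row input yields a zero-row table.
#' @export
jipTable <- function(x, level = c("plant", "plot"),
                     preset = c("full58", "jip56")) {
  level <- match.arg(level)
  preset <- match.arg(preset)
  pn <- jipParameterNames(preset)
  keys <- sampleKeys(x)[, c("genotype", "year", "rep", "plant"), drop = FALSE]
  vals <- fluorValues(x)
  tt <- fluorTimes(x)
  if (ncol(vals) == 0L) {
    out <- cbind(keys, as.data.frame(matrix(numeric(0), 0, length(pn),
                                            dimnames = list(NULL, pn))))
    return(out)
  }
  pm <- t(vapply(seq_len(ncol(vals)), function(j) {
    computeJIP(extractLandmarks(tt, vals[, j]), preset = preset)
  }, numeric(length(pn))))
  plant <- cbind(keys, as.data.frame(pm))
  rownames(plant) <- NULL
  if (level == "plant") return(plant)
  counts <- table(interaction(plant$genotype, plant$year, plant$rep,
                              drop = TRUE))
  if (length(unique(counts)) > 1L)
    warning("unequal plant counts per plot; plot means use available plants")
  agg <- stats::aggregate(plant[pn],
                          by = plant[c("genotype", "year", "rep")],
                          FUN = mean, na.rm = TRUE)
  agg[order(agg$year, agg$rep, agg$genotype), , drop = FALSE]
}

#' Plot-mean transient predictor table
#'
#' Averages the (typically three) plant curves of each plot pointwise,
#' giving one 118-column predictor row per plot for transient-based
#' regression models.
#'
#' @param x a \linkS4class{FluorTransientSet}.
#' @return data.frame with genotype/year/rep keys and one
#'   \code{t_<microseconds>} column per timepoint.
#' @export
transientPlotMeans <- function(x) {
  keys <- sampleKeys(x)
  vals <- t(fluorValues(x))
  colnames(vals) <- sprintf("t_%g", fluorTimes(x) * 1e6)
  df <- cbind(keys[c("genotype", "year", "rep")], as.data.frame(vals))
  agg <- stats::aggregate(df[, -(1:3)],
                          by = df[c("genotype", "year", "rep")],
                          FUN = mean)
  agg[order(agg$year, agg$rep, agg$genotype), , drop = FALSE]
}

#' Read / write transient CSV files
#'
#' \code{writeTransientsCSV} writes the wide export format: one row per
#' plant with key columns \code{genotype, year, rep, plant} followed by
#' \code{t_<microseconds>} reading columns. \code{readTransientsCSV}
#' reads either that wide format or a long format with columns
#' \code{sample_id} (or the four key columns), \code{time_s},
#' \code{value}.
#'
#' @param x a \linkS4class{FluorTransientSet}.
#' @param path CSV file path.
#' @return \code{readTransientsCSV} returns a
#'   \linkS4class{FluorTransientSet}; \code{writeTransientsCSV} returns
#'   \code{path} invisibly.
#' @export
writeTransientsCSV <- function(x, path) {
  df <- cbind(sampleKeys(x)[c("genotype", "year", "rep", "plant")],
              as.data.frame(t(fluorValues(x))))
  names(df)[-(1:4)] <- sprintf("t_%g", fluorTimes(x) * 1e6)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTransientsCSV
#' @export
readTransientsCSV <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  if (all(c("time_s", "value") %in% names(df))) {      # long format
    keycols <- intersect(c("genotype", "year", "rep", "plant", "sample_id"),
                         names(df))
    id <- interaction(df[keycols], drop = TRUE)
    tt <- sort(unique(df$time_s))
    samples <- levels(id)
    vals <- vapply(samples, function(s) {
      sub <- df[id == s, ]
      sub$value[order(sub$time_s)]
    }, numeric(length(tt)))
    keys <- unique(df[keycols])
    keys <- keys[match(samples, interaction(keys, drop = TRUE)), , drop = FALSE]
    if (!"plant" %in% names(keys)) keys$plant <- seq_len(nrow(keys))
    return(fluorTransientSet(tt, vals, keys))
  }
  tcols <- grep("^t_", names(df), value = TRUE)
  if (!length(tcols)) stop("no t_<microseconds> columns found in ", path)
  tt <- as.numeric(sub("^t_", "", tcols)) * 1e-6
  o <- order(tt)
  fluorTransientSet(tt[o], t(as.matrix(df[tcols[o]])),
                    df[c("genotype", "year", "rep", "plant")])
}
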