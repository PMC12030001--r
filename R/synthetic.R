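#' Multi-environment trial design
#'
#' Dimensions of a balanced multi-year maize hybrid trial: genotypes,
#' years (environments), replicates per year, plants measured per plot,
#' fluorescence timepoints per plant, and plot area.
#'
#' @param n_genotypes,n_years,n_reps,n_plants_per_plot,n_timepoints
#'   positive integer counts; defaults describe a 16-hybrid, 3-year,
#'   4-replicate trial with 3 measured plants per plot and 118-point
#'   transients.
#' @param plot_area plot area in square metres (default 7).
#' @param n_jip_parameters nominal size of the derived parameter set
#'   (default 56; see [jipParameterNames()]).
#' @return a validated list of class \code{"trialDesign"}.
#' @export
trialDesign <- function(n_genotypes = 16L, n_years = 3L, n_reps = 4L,
                        n_plants_per_plot = 3L, n_timepoints = 118L,
                        plot_area = 7, n_jip_parameters = 56L) {
  d <- list(n_genotypes = as.integer(n_genotypes),
            n_years = as.integer(n_years), n_reps = as.integer(n_reps),
            n_plants_per_plot = as.integer(n_plants_per_plot),
            n_timepoints = as.integer(n_timepoints),
            plot_area = as.numeric(plot_area),
            n_jip_parameters = as.integer(n_jip_parameters))
  counts <- unlist(d[c("n_genotypes", "n_years", "n_reps",
                       "n_plants_per_plot", "n_timepoints",
                       "n_jip_parameters")])
  if (any(counts < 1L)) stop("all design counts must be >= 1")
  if (d$plot_area <= 0) stop("plot_area must be positive")
  structure(d, class = "trialDesign")
}

#' Base kinetics of the simulated OJIP rise
#'
#' Phenomenological three-exponential model of the fluorescence
#' induction curve: F(t) = F0 + (Fm - F0) * sum_k w_k (1 - exp(-t/tau_k)),
#' whose three saturating phases reproduce the O-J, J-I and I-P plateau
#' structure of dark-adapted leaves.
#'
#' @param F0_base,Fm_base zero-level and maximal fluorescence of the
#'   kinetic model (arbitrary units); \code{Fm_base > F0_base > 0}.
#' @param phase_weights nonnegative 3-vector (O-J, J-I, I-P), summing
#'   to 1 (renormalised if not).
#' @param phase_taus strictly increasing 3-vector of phase time
#'   constants in seconds; defaults 0.3 ms, 8 ms, 120 ms.
#' @return validated list of class \code{"kineticParams"}.
#' @export
kineticParams <- function(F0_base = 500, Fm_base = 4200,
                          phase_weights = c(0.55, 0.25, 0.20),
                          phase_taus = c(3e-4, 8e-3, 0.12)) {
  if (!(Fm_base > F0_base && F0_base > 0))
    stop("require Fm_base > F0_base > 0")
  if (length(phase_weights) != 3L || any(phase_weights < 0))
    stop("phase_weights must be a nonnegative 3-vector")
  if (length(phase_taus) != 3L || any(diff(phase_taus) <= 0))
    stop("phase_taus must be strictly increasing")
  structure(list(F0_base = F0_base, Fm_base = Fm_base,
                 phase_weights = phase_weights / sum(phase_weights),
                 phase_taus = phase_taus),
            class = "kineticParams")
}

## Saturation profile S(t) = sum_k w_k (1 - exp(-t/tau_k)); the measured
## variable-fluorescence fraction reached by time t.
.saturation <- function(times, weights, taus) {
  drop((1 - exp(-outer(times, 1 / taus))) %*% weights)
}

## Solve the model amplitude u = Fm_model/F0_model - 1 so that the
## *measured* Fv/Fm (zero level read at 50 us, maximum at the last grid
## point) equals `target`, for given phase weights/taus.
.solve_amplitude <- function(target, weights, taus,
                             t0 = 50e-6, t1 = 1) {
  s0 <- .saturation(t0, weights, taus)
  s1 <- .saturation(t1, weights, taus)
  den <- s1 * (1 - target) - s0
  if (den <= 0) stop("Fv/Fm target ", target, " not attainable")
  target / den
}

#' Effect specification for the synthetic trial
#'
#' Targets and variance components that drive the generator. Grain yield
#' (GY, t/ha) and grain moisture (GM, %) follow the plot-level linear
#' model y = mu_year + g_i + (gy)_ij + r_k + e with independent normal
#' components; the fluorescence traits are driven by two standardised
#' genotype latents — a "photochemistry" latent acting multiplicatively
#' on log(Fm/F0) (hence on Fv/Fm) and a "curve shape" latent acting
#' multiplicatively on the kinetic phase weights (hence on VJ, M0 and
#' the performance index). The genotype effects of GY and GM are
#' correlated with the photochemistry latent at the configured coupling
#' targets.
#'
#' @param year_means list with numeric vectors \code{gy}, \code{gm},
#'   \code{fvfm}, one value per year.
#' @param gy,gm lists with components \code{var_G, var_GxE, var_rep,
#'   var_e} (squared trait units).
#' @param coupling named vector: genetic-correlation targets
#'   \code{gy_fvfm}, \code{gm_fvfm}, \code{gy_gm}; absolute values <= 1.
#' @param fvfm_sd,shape_sd 3-vectors (genotype, genotype-by-year, plant)
#'   of latent-effect standard deviations, on the relative scale of
#'   log(Fm/F0) and of the log phase-weight tilt respectively.
#' @param shape_coupling correlation between the shape and
#'   photochemistry genotype latents.
#' @param f0_noise_sd lognormal SD of the per-plant overall fluorescence
#'   level (cancels in ratio parameters).
#' @param kinetics base [kineticParams()].
#' @return validated list of class \code{"effectSpec"}.
#' @export
effectSpec <- function(year_means, gy, gm,
                       coupling = c(gy_fvfm = 0.35, gm_fvfm = -0.61,
                                    gy_gm = -0.10),
                       fvfm_sd = c(G = 0.0105, GxE = 0.0095, plant = 0.016),
                       shape_sd = c(G = 0.11, GxE = 0.031, plant = 0.20),
                       shape_coupling = 0.76,
                       f0_noise_sd = 0.05,
                       kinetics = kineticParams()) {
  vars <- c(unlist(gy[c("var_G", "var_GxE", "var_rep", "var_e")]),
            unlist(gm[c("var_G", "var_GxE", "var_rep", "var_e")]),
            fvfm_sd, shape_sd)
  if (any(!is.finite(vars)) || any(vars < 0))
    stop("all variance parameters must be finite and >= 0")
  if (any(abs(c(coupling, shape_coupling)) > 1))
    stop("coupling targets must be within [-1, 1]")
  n_y <- unique(lengths(year_means[c("gy", "gm", "fvfm")]))
  if (length(n_y) != 1L) stop("year_means vectors must have equal length")
  structure(list(year_means = year_means, gy = gy, gm = gm,
                 coupling = coupling, fvfm_sd = fvfm_sd,
                 shape_sd = shape_sd, shape_coupling = shape_coupling,
                 f0_noise_sd = f0_noise_sd, kinetics = kinetics),
            class = "effectSpec")
}

#' Default trial configuration
#'
#' The design and effect specification the package ships as its study
#' conditions: 16 hybrids x 3 years x 4 replicates x 3 plants per plot on
#' 7 m2 plots; GY year means (13.10, 15.73, 13.05) t/ha with variance
#' components (var_G = 0.553, var_GxE = 0.307, var_e = 2.593) plus a small
#' replicate variance; GM year means (21.51, 13.32, 22.60) % with
#' components (1.296, 2.209, 0.795); Fv/Fm year means (0.803, 0.805,
#' 0.810); and genetic-correlation couplings rG(GY, Fv/Fm) = 0.35,
#' rG(GM, Fv/Fm) = -0.61, rG(GY, GM) = -0.10. The fluorescence latent
#' scales are calibrated once so the realised progeny-mean heritabilities
#' are about 0.70 for Fv/Fm and 0.84 for PI_ABS.
#'
#' @return list with elements \code{design} ([trialDesign()]) and
#'   \code{effects} ([effectSpec()]).
#' @export
defaultTrialConfig <- function() {
  list(design = trialDesign(),
       effects = effectSpec(
         year_means = list(gy = c(13.10, 15.73, 13.05),
                           gm = c(21.51, 13.32, 22.60),
                           fvfm = c(0.803, 0.805, 0.810)),
         gy = list(var_G = 0.553, var_GxE = 0.307, var_rep = 0.10,
                   var_e = 2.593),
         gm = list(var_G = 1.296, var_GxE = 2.209, var_rep = 0.00,
                   var_e = 0.795)))
}

#' Generate a complete synthetic trial
#'
#' Draws all genotype / year / genotype-by-year / replicate / plant
#' effects, synthesises one OJIP transient per measured plant from the
#' three-exponential kinetic model, and fills the agronomic plot table
#' (GY, GM, and the plot weight / sample moisture pair that
#' back-computes to GY through the 14 %-moisture standardisation).
#' Blocks are assigned within year by a Latin rotation of genotype
#' groups over replicates, so the block stratum is orthogonal to
#' genotype. Identical \code{design}, \code{effects} and \code{seed}
#' give identical output.
#'
#' @param design a [trialDesign()].
#' @param effects an [effectSpec()].
#' @param seed integer random seed.
#' @return list of class \code{"syntheticTrial"} with elements
#'   \code{transients} (\linkS4class{FluorTransientSet}), \code{agro}
#'   (plot-level data.frame), \code{truth} (sampled effects) and
#'   \code{seed}.
#' @examples
#' cfg <- defaultTrialConfig()
#' trial <- simulateTrial(cfg$design, cfg$effects, seed = 1)
#' dim(fluorValues(trial$transients))  # 118 x 576
#' @export
simulateTrial <- function(design, effects, seed) {
  stopifnot(inherits(design, "trialDesign"), inherits(effects, "effectSpec"))
  if (missing(seed)) stop("seed must be provided")
  if (length(effects$year_means$gy) != design$n_years)
    stop("year_means length must match n_years")
  set.seed(as.integer(seed))
  nG <- design$n_genotypes; nE <- design$n_years; nR <- design$n_reps
  nP <- design$n_plants_per_plot
  genos <- sprintf("H%02d", seq_len(nG))
  years <- 2016L + seq_len(nE)

  ## --- genotype latents -------------------------------------------------
  a  <- rnorm(nG)              # photochemistry latent (drives Fv/Fm)
  u1 <- rnorm(nG); u2 <- rnorm(nG); v <- rnorm(nG)
  cp <- effects$coupling
  r1 <- cp[["gy_fvfm"]]; r2 <- cp[["gm_fvfm"]]
  kap <- (cp[["gy_gm"]] - r1 * r2) / sqrt(1 - r1^2)
  if (r2^2 + kap^2 > 1)
    stop("coupling targets are jointly infeasible")
  g_gy <- sqrt(effects$gy$var_G) * (r1 * a + sqrt(1 - r1^2) * u1)
  g_gm <- sqrt(effects$gm$var_G) *
    (r2 * a + kap * u1 + sqrt(1 - r2^2 - kap^2) * u2)
  sc <- effects$shape_coupling
  cshape <- sc * a + sqrt(1 - sc^2) * v      # shape latent (drives PI)

  ## --- agronomic plot table ---------------------------------------------
  grid <- expand.grid(genotype = genos, year = years, rep = seq_len(nR),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  gi <- match(grid$genotype, genos); yj <- match(grid$year, years)
  ## Latin rotation: 4 genotype groups cycled over replicates
  ngrp <- min(nR, nG)
  grp <- (gi - 1L) %/% max(1L, nG %/% ngrp)
  grid$block <- ((grp + grid$rep - 1L) %% ngrp) + 1L
  ij <- (gi - 1L) * nE + yj
  jk <- (yj - 1L) * nR + grid$rep
  gxe_gy <- rnorm(nG * nE, 0, sqrt(effects$gy$var_GxE))
  gxe_gm <- rnorm(nG * nE, 0, sqrt(effects$gm$var_GxE))
  rep_gy <- rnorm(nE * nR, 0, sqrt(effects$gy$var_rep))
  rep_gm <- rnorm(nE * nR, 0, sqrt(effects$gm$var_rep))
  e_gy <- rnorm(nrow(grid), 0, sqrt(effects$gy$var_e))
  e_gm <- rnorm(nrow(grid), 0, sqrt(effects$gm$var_e))
  gy <- effects$year_means$gy[yj] + g_gy[gi] + gxe_gy[ij] + rep_gy[jk] + e_gy
  gm <- effects$year_means$gm[yj] + g_gm[gi] + gxe_gm[ij] + rep_gm[jk] + e_gm
  gm <- pmin(pmax(gm, 5), 45)   # physical moisture bounds
  plot_weight <- gy * 1000 * 86 / ((100 - gm) * 1e4 / design$plot_area)
  agro <- data.frame(genotype = grid$genotype, year = grid$year,
                     rep = grid$rep, block = grid$block,
                     plot_weight_kg = plot_weight,
                     sample_moisture_pct = gm,
                     gy_t_ha = gy, gm_pct = gm)

  ## --- fluorescence transients ------------------------------------------
  kin <- effects$kinetics
  w0 <- kin$phase_weights; taus <- kin$phase_taus
  tt <- ojipTimeGrid(design$n_timepoints)
  fvfm_t <- effects$year_means$fvfm
  logR_year <- vapply(fvfm_t, function(ph)
    log1p(.solve_amplitude(ph, w0, taus, t0 = 50e-6, t1 = tt[length(tt)])),
    numeric(1))
  fs <- effects$fvfm_sd; ss <- effects$shape_sd
  a_gxe <- rnorm(nG * nE, 0, fs[["GxE"]])
  c_gxe <- rnorm(nG * nE, 0, ss[["GxE"]])
  pl <- expand.grid(plant = seq_len(nP), genotype = genos, year = years,
                    rep = seq_len(nR),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pl <- pl[c("genotype", "year", "rep", "plant")]
  pgi <- match(pl$genotype, genos); pyj <- match(pl$year, years)
  pij <- (pgi - 1L) * nE + pyj
  nPl <- nrow(pl)
  a_pl <- rnorm(nPl, 0, fs[["plant"]])
  c_pl <- rnorm(nPl, 0, ss[["plant"]])
  x_rel <- 1 + fs[["G"]] * a[pgi] + a_gxe[pij] + a_pl
  logR <- logR_year[pyj] * x_rel
  tilt <- ss[["G"]] * cshape[pgi] + c_gxe[pij] + c_pl
  W <- cbind(w0[1] * exp(tilt), w0[2], w0[3] * exp(-tilt))
  W <- W / rowSums(W)
  ## Fv/Fm implied by the plant's log-amplitude under the *base* phase
  ## weights; the shape tilt then reshapes the curve at fixed Fv/Fm, so
  ## the photochemistry and curve-shape channels stay separable.
  t_end <- tt[length(tt)]
  s0b <- .saturation(50e-6, w0, taus); s1b <- .saturation(t_end, w0, taus)
  u_b <- expm1(logR)
  phi <- u_b * (s1b - s0b) / (1 + u_b * s1b)
  e0 <- 1 - exp(-50e-6 / taus); e1 <- 1 - exp(-t_end / taus)
  s0p <- drop(W %*% e0); s1p <- drop(W %*% e1)
  u_p <- phi / (s1p * (1 - phi) - s0p)
  f0 <- kin$F0_base * exp(rnorm(nPl, 0, effects$f0_noise_sd))
  E <- 1 - exp(-outer(tt, 1 / taus))          # n_timepoints x 3
  S <- E %*% t(W)                             # n_timepoints x nPl
  FF <- sweep(sweep(S, 2, u_p, `*`) + 1, 2, f0, `*`)
  transients <- fluorTransientSet(tt, FF, pl)

  structure(list(
    transients = transients, agro = agro,
    truth = list(genotype_gy = setNames(g_gy, genos),
                 genotype_gm = setNames(g_gm, genos),
                 latent_photo = setNames(a, genos),
                 latent_shape = setNames(cshape, genos),
                 gxe_gy = gxe_gy, gxe_gm = gxe_gm,
                 rep_gy = rep_gy, rep_gm = rep_gm,
                 logR_year = logR_year, plant_logR = logR,
                 plant_fvfm = phi, plant_weights = W, plant_f0 = f0),
    seed = as.integer(seed)), class = "syntheticTrial")
}

#' Write a synthetic trial to CSV files
#'
#' Emits \code{transients.csv} (wide plant-level export),
#' \code{agro.csv} (plot table) and \code{truth.csv} (sampled
#' genotype-level effects, long format) into \code{dir}.
#'
#' @param trial a [simulateTrial()] result.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeTrialCSV <- function(trial, dir) {
  stopifnot(inherits(trial, "syntheticTrial"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeTransientsCSV(trial$transients, file.path(dir, "transients.csv"))
  write.csv(trial$agro, file.path(dir, "agro.csv"), row.names = FALSE)
  tr <- trial$truth
  truth <- do.call(rbind, lapply(
    c("genotype_gy", "genotype_gm", "latent_photo", "latent_shape"),
    function(nm) data.frame(effect = nm, level = names(tr[[nm]]),
                            value = unname(tr[[nm]]))))
  write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a run configuration from YAML
#'
#' Convenience wrapper for configuring [runPipeline()] from a YAML file;
#' unspecified fields fall back to the defaults documented there.
#'
#' @param path YAML file.
#' @return named list of configuration fields.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a YAML mapping")
  cfg
}
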