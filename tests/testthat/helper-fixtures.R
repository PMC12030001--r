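# Shared fixtures: all synthetic, built in code at test time.

# A reduced trial for fast structural tests.
small_trial <- function(seed = 11L, n_genotypes = 4L, n_years = 2L,
                        n_reps = 2L, n_plants = 2L, n_timepoints = 40L) {
  cfg <- defaultTrialConfig()
  des <- trialDesign(n_genotypes = n_genotypes, n_years = n_years,
                     n_reps = n_reps, n_plants_per_plot = n_plants,
                     n_timepoints = n_timepoints)
  eff <- cfg$effects
  eff$year_means <- lapply(eff$year_means, function(v)
    v[seq_len(n_years)])
  simulateTrial(des, eff, seed = seed)
}

# Balanced plot table with known independent normal effects; block is a
# Latin rotation of genotype groups so it is orthogonal to genotype.
balanced_table <- function(g = 8L, e = 3L, r = 4L, mu = 10,
                           sd_g = 1, sd_gxe = 0.5, sd_rep = 0.3,
                           sd_e = 1, seed = 1L) {
  set.seed(seed)
  tab <- expand.grid(genotype = sprintf("G%02d", seq_len(g)),
                     year = seq_len(e), rep = seq_len(r),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  gi <- match(tab$genotype, sort(unique(tab$genotype)))
  ngrp <- min(r, g)
  grp <- (gi - 1L) %/% max(1L, g %/% ngrp)
  tab$block <- ((grp + tab$rep - 1L) %% ngrp) + 1L
  geff <- rnorm(g, 0, sd_g)
  gxe <- matrix(rnorm(g * e, 0, sd_gxe), g, e)
  reff <- matrix(rnorm(e * r, 0, sd_rep), e, r)
  tab$y <- mu + geff[gi] + gxe[cbind(gi, tab$year)] +
    reff[cbind(tab$year, tab$rep)] + rnorm(nrow(tab), 0, sd_e)
  tab
}

# One synthetic OJIP curve from the saturating-exponential model.
test_curve <- function(times = ojipTimeGrid(),
                       F0 = 500, Fv = 2000,
                       w = c(0.55, 0.25, 0.20),
                       tau = c(3e-4, 8e-3, 0.12)) {
  S <- drop((1 - exp(-outer(times, 1 / tau))) %*% (w / sum(w)))
  F0 + Fv * S
}

# Landmarks giving prescribed phi_Po, VJ and M0 exactly.
landmarks_from <- function(phi_Po, VJ, M0, Fm = 2000, VI = NULL) {
  F0 <- (1 - phi_Po) * Fm
  Fv <- Fm - F0
  if (is.null(VI)) VI <- min(1, VJ + 0.25)
  list(F0 = F0, F1 = F0, F2 = F0 + 0.02 * Fv,
       F3 = F0 + M0 * (Fm - F0) / 4,
       F4 = F0 + VJ * Fv, F5 = F0 + VI * Fv,
       Fm = Fm, t_Fm = 1, area = 0.3 * Fv)
}
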