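#!/usr/bin/env Rscript

# Calibration harness for the qualitative kinetic defaults.
#
# The anchored constants (basal uPAR production c, eps_PAI = 0.01,
# eps_uPAR = 0.0095, initial fibrin-bound concentrations, CPM and
# invasion parameters) are fixed; the remaining kinetics are chosen so
# that, at reduced scale:
#   1. the baseline is quiet: with latent TGFbeta1 absent, fibrin loss
#      (structurally equal to the plasmin activation rate) keeps the
#      monolayer's slow sinking inside the quantifier's excluded band;
#   2. ignited fronts clear about one site per 50-100 MCS;
#   3. active TGFbeta1 is short-ranged, so ignition stays local;
#   4. the TGF-induction threshold k_m3 sits at the upper tail of the
#      baseline perimeter-TGF distribution, making ignition a rare,
#      expression-dependent event.
#
# Stage 1 measures that baseline tail with induction switched off;
# stage 2 verifies the resulting gradation in the basal expression rate
# and the latent-TGFbeta1 null.  Usage:
#   Rscript scripts/calibrate.R [--reps N]

suppressPackageStartupMessages(library(angiosprout))

args <- commandArgs(trailingOnly = TRUE)
reps <- if (length(i <- which(args == "--reps")) == 1)
  as.integer(args[i + 1]) else 3L

reduced <- function(kin, mcs = 1500, seed = 1, ...) {
  sim_config(width = 250, height = 75, n_cells = 25, mcs_total = mcs,
             record_every = mcs, seed = seed, kinetics = kin, ...)
}

## Stage 1: baseline perimeter-TGF distribution (induction off) ---------
kin0 <- kinetic_params(k_u3 = 0)
cfg <- reduced(kin0, mcs = 800, seed = 5)
set.seed(cfg$seed)
sim <- initialize_simulation(cfg)
tgf_sums <- c()
for (i in 1:800) {
  sim <- simulation_step(sim)
  if (i > 300 && i %% 20 == 0) {
    cs <- angiosprout:::cpp_cell_sums(sim$state$sigma, sim$state$type,
                                      sim$fields$TGF, sim$fields$PAI)
    tgf_sums <- c(tgf_sums, cs$tgf_sum[sim$state$type == 1])
  }
}
q <- quantile(tgf_sums, c(0.5, 0.9, 0.99, 1))
cat("baseline perimeter-TGF sums (c = 0.005, induction off):\n")
print(signif(q, 3))
kin <- kinetic_params()
cat(sprintf("default k_m3 = %g (threshold T = %.4f) sits at the tail\n\n",
            kin$k_m3, sqrt(kin$k_m3 * kin$c / kin$k_u3)))

## Stage 2: expression gradation and the latent-TGFbeta1 null -----------
for (cc in c(0.001, 0.003, 0.005)) {
  sw <- run_sweep("c", cc, n_reps = reps, base_config = reduced(kinetic_params()))
  cat(sprintf("c = %-6g sprouting %5.1f%%  fibrinolysis %5.1f%%\n",
              cc, sw$summary$sprouting_pct, sw$summary$fibrinolysis_mean))
}
null_cfg <- reduced(kinetic_params(), seed = 2)
null_cfg$f_plg_ltgf <- 0
null_cfg$f_plg <- 1
sw0 <- run_sweep("c", 0.005, n_reps = reps, base_config = null_cfg)
cat(sprintf("no latent TGF  sprouting %5.1f%%  fibrinolysis %5.1f%%\n",
            sw0$summary$sprouting_pct, sw0$summary$fibrinolysis_mean))
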