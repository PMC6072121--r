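# Operator-splitting scheduler, initialization, mitosis and dosing.

#' Fibrin invasion penalty parameters
#'
#' Copies into fibrin-type sites incur an energy penalty
#' `p / (1 + exp(-E * (f - m)))` when the total fibrin concentration `f`
#' at the invaded site exceeds `theta_fibrin`; below the threshold fibrin
#' does not hinder invasion.
#'
#' @param p Penalty amplitude.
#' @param E Sigmoid steepness.
#' @param m Sigmoid midpoint concentration.
#' @param theta_fibrin Concentration below which invasion is free.
#' @return Object of class `invasion_params`.
#' @export
invasion_params <- function(p = 1000, E = 10, m = 0.5, theta_fibrin = 0.3) {
  structure(list(p = p, E = E, m = m, theta_fibrin = theta_fibrin),
            class = "invasion_params")
}

#' Fibrin obstruction energy
#'
#' @param f Total fibrin concentration in `[0, 1]` (vectorized).
#' @param params An [invasion_params()].
#' @return Dimensionless penalty, zero at or below the threshold.
#' @export
invasion_penalty <- function(f, params = invasion_params()) {
  ifelse(f > params$theta_fibrin,
         params$p / (1 + exp(-params$E * (f - params$m))), 0)
}

#' Simulation configuration
#'
#' Collects lattice geometry, CPM parameters, kinetic parameters, initial
#' concentrations and the schedule.  The default geometry is a
#' 500 x 150-site domain (1000 um x 300 um at 2 um per site) with fifty
#' 200-site endothelial cells in a monolayer on a fibrin block filling
#' the lower two-thirds of the interior, run for 6000 MCS (10 days at
#' 2.5 min/MCS).
#'
#' @param width,height Lattice dimensions in sites (including the one-site
#'   border frame).
#' @param n_cells Number of endothelial cells in the initial monolayer.
#' @param target_area Cell target area in sites (200 sites = 800 um^2).
#' @param fibrin_fraction Fraction of the interior height initially
#'   occupied by fibrin.
#' @param mcs_total Number of Monte Carlo steps to run.
#' @param cpm A [cpm_params()].
#' @param kinetics A [kinetic_params()].
#' @param invasion An [invasion_params()].
#' @param f_plg_ltgf,f_ltgf,f_plg Initial concentrations of the
#'   fibrin-bound species on fibrin sites.  The defaults load every fibrin
#'   site with the doubly-bound complex at 1 RU; the validation sweeps
#'   lower one moiety while keeping totals at 1
#'   (`f_plg_ltgf + f_ltgf = 1` for plasminogen depletion,
#'   `f_plg_ltgf + f_plg = 1` for latent-TGFbeta1 depletion).
#' @param tgf_dose Uniform initial concentration of active TGFbeta1, also
#'   re-applied every `redose_period` MCS when positive.
#' @param redose_period Dosing period in MCS; 1152 MCS is two days at
#'   2.5 min/MCS.
#' @param pde_substeps Reaction-diffusion substeps per MCS (10 substeps of
#'   0.1 MCS = 15 s each).
#' @param p_mitosis Division probability per eligible check.
#' @param r_mitosis Division is allowed when the fraction of a cell's
#'   membrane in contact with other cells is below this threshold.
#' @param mitosis_every Division check period in MCS.
#' @param minutes_per_mcs Real-time equivalent of one MCS.
#' @param pai_equilibrium Start the PAI-1 field at its domain-wide
#'   mass-balance steady state, representing secretion during the
#'   pre-culture day before stimulation (default `TRUE`); `FALSE` starts
#'   it at zero.
#' @param seed RNG seed used by [run_simulation()]; `NULL` leaves the RNG
#'   state untouched.
#' @param record_every Trajectory recording cadence in MCS.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(width = 500, height = 150, n_cells = 50,
                       target_area = 200, fibrin_fraction = 2 / 3,
                       mcs_total = 6000,
                       cpm = cpm_params(), kinetics = kinetic_params(),
                       invasion = invasion_params(),
                       f_plg_ltgf = 1, f_ltgf = 0, f_plg = 0,
                       tgf_dose = 0, redose_period = 1152,
                       pde_substeps = 10,
                       p_mitosis = 0.6, r_mitosis = 0.35,
                       mitosis_every = 10, minutes_per_mcs = 2.5,
                       pai_equilibrium = TRUE,
                       seed = 1L, record_every = 200) {
  stopifnot(mcs_total >= 0, n_cells >= 1, pde_substeps >= 1)
  dt_pde <- 1 / pde_substeps
  for (nm in c("D_plg", "D_ltgf", "D_tgf", "D_pai")) {
    if (kinetics[[nm]] * dt_pde >= 0.25)
      stop("lattice diffusion number for ", nm,
           " violates the stability bound 0.25")
  }
  structure(list(width = width, height = height, n_cells = n_cells,
                 target_area = target_area,
                 fibrin_fraction = fibrin_fraction, mcs_total = mcs_total,
                 cpm = cpm, kinetics = kinetics, invasion = invasion,
                 f_plg_ltgf = f_plg_ltgf, f_ltgf = f_ltgf, f_plg = f_plg,
                 tgf_dose = tgf_dose, redose_period = redose_period,
                 pde_substeps = pde_substeps, dt_pde = dt_pde,
                 p_mitosis = p_mitosis, r_mitosis = r_mitosis,
                 mitosis_every = mitosis_every,
                 minutes_per_mcs = minutes_per_mcs,
                 pai_equilibrium = pai_equilibrium,
                 seed = seed, record_every = record_every),
            class = "sim_config")
}

#' Set up the monolayer-on-fibrin initial condition
#'
#' Builds the lattice: a one-site border frame; a single fibrin identifier
#' filling the lower part of the interior; `n_cells` equal cells in one
#' row on top of the fibrin surface; medium above; and a static cell patch
#' embedded in each side wall at monolayer level that glues the cell layer
#' to the boundary.  Fibrin sites receive the configured fibrin-bound
#' concentrations; active TGFbeta1 is applied uniformly when dosed; all
#' cells start at the uPAR steady state `c / eps_upar`.
#'
#' @param config A [sim_config()].
#' @return Object of class `sprout_sim`: the lattice state, field set,
#'   projected uPAR field, division log and bookkeeping of the initial
#'   fibrin region.
#' @export
initialize_simulation <- function(config) {
  W <- config$width
  H <- config$height
  iw <- W - 2L  # interior width
  ih <- H - 2L
  h_f <- round(config$fibrin_fraction * ih)
  cell_w <- iw / config$n_cells
  cell_h <- max(2L, round(config$target_area / cell_w))
  if (h_f + cell_h > ih)
    stop("domain too small to fit the fibrin block and the monolayer")

  MED <- 1L; BOR <- 2L; FIB <- 3L; PATCH_L <- 4L; PATCH_R <- 5L
  n_ids <- 5L + config$n_cells
  sigma <- matrix(MED, nrow = H, ncol = W)
  sigma[1, ] <- BOR; sigma[H, ] <- BOR
  sigma[, 1] <- BOR; sigma[, W] <- BOR
  fib_rows <- 2:(h_f + 1)
  sigma[fib_rows, 2:(W - 1)] <- FIB
  mono_rows <- (h_f + 2):(h_f + 1 + cell_h)
  # equal-width column blocks per cell (rounded split of the interior);
  # every cell starts at exactly its target area, topping up any remainder
  # on one extra row so no cell begins under pressure
  breaks <- round(seq(2, W, length.out = config$n_cells + 1))
  for (i in seq_len(config$n_cells)) {
    cols <- breaks[i]:(breaks[i + 1] - 1)
    w_i <- length(cols)
    h0 <- config$target_area %/% w_i
    rem <- config$target_area - h0 * w_i
    if (h_f + 1 + h0 + (rem > 0) > H - 1)
      stop("domain too small to fit the fibrin block and the monolayer")
    sigma[(h_f + 2):(h_f + 1 + h0), cols] <- 5L + i
    if (rem > 0)
      sigma[h_f + 2 + h0, cols[seq_len(rem)]] <- 5L + i
  }
  sigma[mono_rows, 1] <- PATCH_L
  sigma[mono_rows, W] <- PATCH_R

  type <- c("medium", "border", "fibrin", "cell patch", "cell patch",
            rep("cell", config$n_cells))
  upar0 <- config$kinetics$c / config$kinetics$eps_upar
  state <- lattice_state(sigma, type,
                         target_area = c(rep(0, 5),
                                         rep(config$target_area,
                                             config$n_cells)),
                         upar = c(rep(0, 5), rep(upar0, config$n_cells)))

  fib_mask <- matrix(FALSE, H, W)
  fib_mask[fib_rows, 2:(W - 1)] <- TRUE
  fields <- field_set(W, H)
  fields$F_PLG_LTGF[fib_mask] <- config$f_plg_ltgf
  fields$F_LTGF[fib_mask] <- config$f_ltgf
  fields$F_PLG[fib_mask] <- config$f_plg
  if (config$pai_equilibrium && config$kinetics$eps_pai > 0) {
    # cells secrete PAI-1 during the pre-culture day before stimulation;
    # start the field at its domain-wide mass-balance steady state
    n_cell_sites <- sum(state$type[sigma] == TYPE_CODES[["cell"]])
    fields$PAI[] <- config$kinetics$alpha * n_cell_sites /
      (config$kinetics$eps_pai * W * H)
  }
  if (config$tgf_dose > 0) fields$TGF[] <- config$tgf_dose

  structure(list(state = state, fields = fields,
                 upar_field = project_upar_field(state),
                 config = config, mcs = 0L,
                 events = empty_events(),
                 initial_fibrin = fib_mask,
                 fibrin_rows = fib_rows),
            class = "sprout_sim")
}

empty_events <- function() {
  data.frame(mcs = integer(), parent = integer(), daughter = integer(),
             parent_birth = integer(), parent_upar = numeric())
}

deep_copy_sim <- function(sim) {
  sim$state <- copy_state(sim$state)
  sim$fields <- duplicate_fields(sim$fields)
  sim$upar_field <- sim$upar_field + 0
  sim
}

# Contact-inhibited mitosis, mutating sim$state in place.
divide_inplace <- function(sim) {
  cfg <- sim$config
  st <- sim$state
  cr <- cpp_contact_ratio(st$sigma, st$type)
  is_cell <- st$type == TYPE_CODES[["cell"]] & st$area >= 2L
  ratio <- ifelse(cr$total > 0, cr$cell_contact / cr$total, 0)
  eligible <- which(is_cell & ratio < cfg$r_mitosis)
  for (id in eligible) {
    if (runif(1) >= cfg$p_mitosis) next
    new_id <- length(st$type) + 1L
    res <- cpp_split_cell(st$sigma, id, new_id)
    if (res$daughter == 0L) next
    st$type <- c(st$type, TYPE_CODES[["cell"]])
    st$target_area <- c(st$target_area, st$target_area[id])
    st$area[id] <- as.integer(res$parent)
    st$area <- c(st$area, as.integer(res$daughter))
    st$upar <- c(st$upar, st$upar[id])
    sim$events <- rbind(sim$events, data.frame(
      mcs = sim$mcs, parent = id, daughter = new_id,
      parent_birth = st$birth[id], parent_upar = st$upar[id]))
    st$birth[id] <- sim$mcs
    st$birth <- c(st$birth, sim$mcs)
  }
  sim$state <- st
  sim
}

#' Contact-inhibited cell division
#'
#' Every cell whose membrane fraction in contact with other cells,
#' `R = cell-cell boundary pairs / all boundary pairs`, is below
#' `r_mitosis` divides with probability `p_mitosis` over its short
#' principal axis.  Both daughters keep the parent's target area and uPAR
#' level.  Intended to be invoked every `mitosis_every` MCS.
#'
#' @param sim A `sprout_sim`.
#' @return The updated `sprout_sim` with new division events appended to
#'   `sim$events`.
#' @export
maybe_divide <- function(sim) {
  divide_inplace(deep_copy_sim(sim))
}

#' Reset the active TGFbeta1 field to a dose
#'
#' Mimics refreshing the TGFbeta1-supplemented medium: at every multiple
#' of `period` MCS the TGF field is set uniformly to `dose`; other fields
#' are untouched.  At other times this is a no-op.
#'
#' @param fields A [field_set()].
#' @param dose Dose in RU.
#' @param mcs Current MCS.
#' @param period Dosing period in MCS.
#' @return The (possibly updated) `field_set`.
#' @export
redose_tgf <- function(fields, dose, mcs, period) {
  if (dose > 0 && mcs > 0 && mcs %% period == 0) {
    fields$TGF <- matrix(dose, nrow(fields$TGF), ncol(fields$TGF))
  }
  fields
}

step_inplace <- function(sim) {
  cfg <- sim$config
  st <- sim$state
  # (1) one Monte Carlo step at frozen chemistry
  fib_tot <- total_fibrin(sim$fields)
  cpp_monte_carlo_step(st$sigma, st$type, st$area, st$target_area,
                       cfg$cpm$J, cfg$cpm$lambda_A, cfg$cpm$mu,
                       cfg$cpm$h_connectivity, fib_tot,
                       cfg$invasion$p, cfg$invasion$E, cfg$invasion$m,
                       cfg$invasion$theta_fibrin)
  # (2) one Euler step of the per-cell uPAR equations, then re-project
  st <- ode_step(st, sim$fields, cfg$kinetics, dt = 1)
  sim$state <- st
  cpp_project_upar(st$sigma, st$type, st$upar, sim$upar_field)
  # (3) reaction-diffusion substeps
  cmask <- cell_mask(st)
  for (k in seq_len(cfg$pde_substeps)) {
    cpp_reaction_step(sim$fields$F, sim$fields$PLG, sim$fields$LTGF,
                      sim$fields$TGF, sim$fields$PAI, sim$fields$F_PLG,
                      sim$fields$F_LTGF, sim$fields$F_PLG_LTGF,
                      sim$fields$F_PLS, sim$fields$F_PLS_LTGF,
                      sim$upar_field, cmask, cfg$kinetics, cfg$dt_pde)
    for (nm in names(DIFFUSING)) {
      cpp_diffusion_step(sim$fields[[nm]], cfg$kinetics[[DIFFUSING[[nm]]]],
                         cfg$dt_pde, 1)
    }
  }
  sim$mcs <- sim$mcs + 1L
  # (4) division check on schedule
  if (sim$mcs %% cfg$mitosis_every == 0L) sim <- divide_inplace(sim)
  # (5) scheduled TGFbeta1 re-dosing
  sim$fields <- redose_tgf(sim$fields, cfg$tgf_dose, sim$mcs,
                           cfg$redose_period)
  sim
}

#' Advance the simulation by one time step
#'
#' One operator-splitting step: a Monte Carlo step of the CPM at frozen
#' chemistry, one Euler step of the uPAR equations followed by
#' re-projection of the uPAR field, `pde_substeps` reaction-diffusion
#' substeps, the division check on its schedule, and scheduled TGFbeta1
#' re-dosing.
#'
#' @param sim A `sprout_sim` from [initialize_simulation()].
#' @return The advanced `sprout_sim`.
#' @export
simulation_step <- function(sim) {
  step_inplace(deep_copy_sim(sim))
}

#' Run a full simulation
#'
#' Seeds the RNG, initializes the monolayer-on-fibrin condition and
#' advances `mcs_total` steps, recording a trajectory of the morphometrics
#' at the configured cadence.
#'
#' @param config A [sim_config()].
#' @param keep_sim Keep the final `sprout_sim` in the result (default
#'   `TRUE`; set `FALSE` to save memory in large sweeps).
#' @return Object of class `sprout_run`: `metrics` (final angiogenesis
#'   level, sprouted flag, fibrinolysis percentage, division count),
#'   `trajectory` (data frame), `events` (division log) and, optionally,
#'   the final `sim`.
#' @export
run_simulation <- function(config, keep_sim = TRUE) {
  if (!is.null(config$seed)) set.seed(config$seed)
  sim <- initialize_simulation(config)
  traj <- list(snapshot_row(sim))
  while (sim$mcs < config$mcs_total) {
    sim <- step_inplace(sim)
    if (sim$mcs %% config$record_every == 0L || sim$mcs == config$mcs_total)
      traj[[length(traj) + 1L]] <- snapshot_row(sim)
  }
  level <- angiogenesis_level(sim$state, sim$fibrin_rows)
  metrics <- list(angiogenesis_level = level,
                  sprouted = level > 0,
                  fibrinolysis_pct = fibrinolysis_percentage(
                    sim$state, sim$initial_fibrin),
                  monolayer_descent = monolayer_descent(sim$state,
                                                        sim$fibrin_rows),
                  n_divisions = nrow(sim$events))
  structure(list(metrics = metrics,
                 trajectory = do.call(rbind, traj),
                 events = sim$events,
                 sim = if (keep_sim) sim else NULL),
            class = "sprout_run")
}

snapshot_row <- function(sim) {
  is_cell <- sim$state$type == TYPE_CODES[["cell"]] & sim$state$area > 0L
  level <- angiogenesis_level(sim$state, sim$fibrin_rows)
  data.frame(mcs = sim$mcs,
             angiogenesis_level = level,
             sprouted = level > 0,
             fibrinolysis_pct = fibrinolysis_percentage(sim$state,
                                                        sim$initial_fibrin),
             n_cells = sum(is_cell),
             mean_upar = mean(sim$state$upar[is_cell]),
             max_upar = max(sim$state$upar[is_cell]),
             total_fibrin = sum(total_fibrin(sim$fields)))
}

#' @export
print.sprout_run <- function(x, ...) {
  cat("Endothelial sprouting simulation\n")
  cat(sprintf("  MCS run            : %d\n", max(x$trajectory$mcs)))
  cat(sprintf("  angiogenesis level : %.3f\n",
              x$metrics$angiogenesis_level))
  cat(sprintf("  sprouted           : %s\n", x$metrics$sprouted))
  cat(sprintf("  fibrinolysis       : %.2f%%\n", x$metrics$fibrinolysis_pct))
  cat(sprintf("  divisions          : %d\n", x$metrics$n_divisions))
  invisible(x)
}
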