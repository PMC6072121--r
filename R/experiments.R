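# Scripted in-silico experiments: parameter sweeps with replicate
# statistics and the qualitative validation suite.

SWEEP_PARAMS <- c("c", "eps_upar", "eps_pai", "plg0", "ltgf0", "tgf_dose")

apply_sweep_value <- function(config, param, value) {
  switch(param,
         c = { config$kinetics$c <- value; config },
         eps_upar = { config$kinetics$eps_upar <- value; config },
         eps_pai = { config$kinetics$eps_pai <- value; config },
         plg0 = {
           # plasminogen depletion: total plasminogen and latent-TGFbeta1
           # moieties on fibrin kept at 1
           config$f_plg_ltgf <- value
           config$f_ltgf <- 1 - value
           config$f_plg <- 0
           config
         },
         ltgf0 = {
           # latent-TGFbeta1 depletion (the LMW-fibrin analogue)
           config$f_plg_ltgf <- value
           config$f_plg <- 1 - value
           config$f_ltgf <- 0
           config
         },
         tgf_dose = { config$tgf_dose <- value; config },
         stop("unknown sweep parameter: ", param))
}

#' Run a parameter sweep with replicate statistics
#'
#' Runs `n_reps` seeded replicates of [run_simulation()] at each value of
#' one swept parameter and summarizes the morphometrics per value.
#' Replicate seeds are derived deterministically from the base
#' configuration's seed and are shared across values (common random
#' numbers), so per-seed differences between values are paired.
#'
#' Swept parameters: `"c"` (basal uPAR expression), `"eps_upar"` and
#' `"eps_pai"` (decay rates), `"plg0"` and `"ltgf0"` (initial fibrin-bound
#' plasminogen / latent-TGFbeta1, with the complementary moiety raised to
#' keep totals at 1), and `"tgf_dose"` (uniform active-TGFbeta1 dosing,
#' refreshed every `redose_period`).
#'
#' @param param One of the sweep parameter names above.
#' @param values Numeric grid of parameter values.
#' @param n_reps Replicates per value.
#' @param base_config A [sim_config()]; its `seed` seeds the sweep.
#' @return Object of class `sweep_result` with `runs` (one row per run)
#'   and `summary` (one row per value: sprouting percentage, mean
#'   angiogenesis level over sprouted runs, mean and SD of the
#'   fibrinolysis percentage).
#' @export
run_sweep <- function(param, values, n_reps, base_config) {
  param <- match.arg(param, SWEEP_PARAMS)
  set.seed(base_config$seed)
  seeds <- sample.int(.Machine$integer.max, n_reps)
  runs <- list()
  for (vi in seq_along(values)) {
    cfg <- apply_sweep_value(base_config, param, values[vi])
    for (ri in seq_len(n_reps)) {
      cfg$seed <- seeds[ri]
      res <- run_simulation(cfg, keep_sim = FALSE)
      cyc <- cell_cycle_stats(res$events, cfg$minutes_per_mcs)
      runs[[length(runs) + 1L]] <- data.frame(
        param = param, value = values[vi], rep = ri, seed = seeds[ri],
        angiogenesis_level = res$metrics$angiogenesis_level,
        sprouted = res$metrics$sprouted,
        fibrinolysis_pct = res$metrics$fibrinolysis_pct,
        monolayer_descent = res$metrics$monolayer_descent,
        n_divisions = res$metrics$n_divisions,
        cycle_days = if (cyc$defined) cyc$mean_days else NA_real_)
    }
  }
  runs <- do.call(rbind, runs)
  structure(list(param = param, values = values, n_reps = n_reps,
                 runs = runs, summary = summarize_sweep(runs)),
            class = "sweep_result")
}

summarize_sweep <- function(runs) {
  do.call(rbind, lapply(split(runs, runs$value), function(d) {
    sp <- sprouting_percentage(d$angiogenesis_level)
    data.frame(value = d$value[1],
               n = nrow(d),
               sprouting_pct = sp$percentage,
               mean_level_sprouted = sp$mean_level_sprouted,
               fibrinolysis_mean = mean(d$fibrinolysis_pct),
               fibrinolysis_sd = stats::sd(d$fibrinolysis_pct))
  }))
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Parameter sweep over %s (%d replicates per value)\n",
              x$param, x$n_reps))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

# Paired one-sided trend check between the two extreme grid values, using
# the seed pairing of run_sweep: for `metric` expected `increasing` in the
# parameter, counts per-seed sign of (high - low) and reports an exact
# binomial p-value alongside the difference of means.
trend_test <- function(sweep, metric, increasing = TRUE) {
  runs <- sweep$runs
  lo <- runs[runs$value == min(runs$value), ]
  hi <- runs[runs$value == max(runs$value), ]
  lo <- lo[order(lo$rep), ]
  hi <- hi[order(hi$rep), ]
  d <- hi[[metric]] - lo[[metric]]
  if (!increasing) d <- -d
  n_up <- sum(d > 0)
  n_dn <- sum(d < 0)
  p <- stats::binom.test(n_up, n_up + n_dn, alternative = "greater")$p.value
  list(metric = metric, n_up = n_up, n_down = n_dn, n_tied = sum(d == 0),
       mean_diff = mean(d), p_value = if (n_up + n_dn > 0) p else 1)
}

#' Qualitative validation suite
#'
#' Re-runs the model's qualitative validation experiments and reports a
#' pass/fail per expected trend:
#'
#' * plasminogen depletion: sprouting and fibrinolysis increase with the
#'   initial fibrin-bound plasminogen concentration;
#' * uPAR decay: both decrease as the uPAR decay rate increases;
#' * PAI-1 decay: fibrinolysis increases monotonically while sprouting
#'   is biphasic: none at low decay (strong PAI-1), sprouting at the
#'   default, global monolayer lowering (large median fibrin-surface
#'   descent) at high decay;
#' * latent-TGFbeta1 depletion (the LMW vs HMW fibrin prediction):
#'   sprouting decreases at low initial fibrin-bound latent TGFbeta1;
#' * no-LTGF null: with no fibrin-bound latent TGFbeta1 at a parameter
#'   set that sprouts well with it, no replicate sprouts;
#' * TGFbeta1 dosing: biphasic, with low doses enhancing sprouting and
#'   the highest dose lowering the complete monolayer (large median
#'   descent with fibrinolysis at least as high as undosed).
#'
#' @param base_config A [sim_config()]; scaled-down geometries are
#'   accepted and trends are assessed on replicate statistics.
#' @param n_reps Replicates per grid value.
#' @param grids Optional named list overriding the default value grids
#'   (`plg0`, `eps_upar`, `eps_pai`, `ltgf0`, `tgf_dose`).
#' @return Data frame of checks with observed statistics and a `pass`
#'   flag, plus the underlying `sweep_result`s as an attribute.
#' @export
run_validation_suite <- function(base_config, n_reps = 20, grids = list()) {
  g <- utils::modifyList(list(
    plg0 = c(0.1, 1),
    eps_upar = c(0.0095, 0.03),
    eps_pai = c(0.002, 0.01, 0.3),
    ltgf0 = c(0, 1),
    tgf_dose = c(0, 0.5, 10, 1000)), grids)

  null_cfg <- base_config
  null_cfg$kinetics$c <- 0.005
  sweeps <- list(
    plg0 = run_sweep("plg0", g$plg0, n_reps, base_config),
    eps_upar = run_sweep("eps_upar", g$eps_upar, n_reps, base_config),
    eps_pai = run_sweep("eps_pai", g$eps_pai, n_reps, base_config),
    ltgf0 = run_sweep("ltgf0", g$ltgf0, n_reps, null_cfg),
    tgf_dose = run_sweep("tgf_dose", g$tgf_dose, n_reps, base_config))

  checks <- list()
  add <- function(name, stat, pass)
    checks[[length(checks) + 1L]] <<- data.frame(check = name,
                                                 statistic = stat,
                                                 pass = pass)
  sp <- function(sw) sw$summary$sprouting_pct
  fib <- function(sw) sw$summary$fibrinolysis_mean

  add("plasminogen: sprouting increases with initial F_PLG",
      diff(range(sp(sweeps$plg0))) *
        sign(sp(sweeps$plg0)[length(g$plg0)] - sp(sweeps$plg0)[1]),
      sp(sweeps$plg0)[length(g$plg0)] > sp(sweeps$plg0)[1])
  add("plasminogen: fibrinolysis increases with initial F_PLG",
      trend_test(sweeps$plg0, "fibrinolysis_pct", TRUE)$mean_diff,
      trend_test(sweeps$plg0, "fibrinolysis_pct", TRUE)$p_value < 0.05)
  add("uPAR decay: sprouting decreases",
      sp(sweeps$eps_upar)[1] - sp(sweeps$eps_upar)[length(g$eps_upar)],
      sp(sweeps$eps_upar)[length(g$eps_upar)] < sp(sweeps$eps_upar)[1] ||
        all(sp(sweeps$eps_upar) == 0))
  add("uPAR decay: fibrinolysis decreases",
      trend_test(sweeps$eps_upar, "fibrinolysis_pct", FALSE)$mean_diff,
      trend_test(sweeps$eps_upar, "fibrinolysis_pct", FALSE)$p_value < 0.05)
  pai_sp <- sp(sweeps$eps_pai)
  pai_desc <- vapply(split(sweeps$eps_pai$runs, sweeps$eps_pai$runs$value),
                     function(d) mean(d$monolayer_descent), numeric(1))
  add("PAI-1 decay: no sprouting at strong PAI-1 (low decay)",
      pai_sp[1], pai_sp[1] == 0 && pai_sp[2] > 0)
  add("PAI-1 decay: global monolayer lowering at high decay",
      pai_desc[length(pai_desc)],
      pai_desc[length(pai_desc)] > pai_desc[2] + 2)
  add("PAI-1 decay: fibrinolysis increases",
      trend_test(sweeps$eps_pai, "fibrinolysis_pct", TRUE)$mean_diff,
      trend_test(sweeps$eps_pai, "fibrinolysis_pct", TRUE)$p_value < 0.05)
  add("LTGF depletion: sprouting lower without fibrin-bound latent TGF",
      sp(sweeps$ltgf0)[length(g$ltgf0)] - sp(sweeps$ltgf0)[1],
      sp(sweeps$ltgf0)[1] <= sp(sweeps$ltgf0)[length(g$ltgf0)])
  add("no-LTGF null: zero sprouted replicates",
      sp(sweeps$ltgf0)[1],
      sp(sweeps$ltgf0)[1] == 0)
  dose_sp <- sp(sweeps$tgf_dose)
  dose_fib <- fib(sweeps$tgf_dose)
  dose_desc <- vapply(split(sweeps$tgf_dose$runs, sweeps$tgf_dose$runs$value),
                      function(d) mean(d$monolayer_descent), numeric(1))
  add("TGF dosing: low dose enhances sprouting over no dose",
      max(dose_sp[2:(length(dose_sp) - 1)]) - dose_sp[1],
      max(dose_sp[2:(length(dose_sp) - 1)]) > dose_sp[1])
  add("TGF dosing: highest dose lowers the monolayer",
      dose_desc[length(dose_desc)],
      dose_desc[length(dose_desc)] > dose_desc[1] + 2 &&
        dose_fib[length(dose_fib)] >= dose_fib[1])
  report <- do.call(rbind, checks)
  attr(report, "sweeps") <- sweeps
  report
}
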