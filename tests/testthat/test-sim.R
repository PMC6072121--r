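# Engine-level behavior: invasion penalty, initialization, mitosis,
# operator splitting, dosing and whole-run invariants.

small_cfg <- function(...) {
  sim_config(width = 120, height = 70, n_cells = 12, mcs_total = 50,
             record_every = 25, seed = 1, ...)
}

test_that("invasion penalty is gated at theta and sigmoidal above it", {
  expect_equal(invasion_penalty(0.2), 0)
  expect_equal(invasion_penalty(0.3), 0)
  expect_equal(invasion_penalty(0.5), 500)
  expect_equal(invasion_penalty(1.0), 1000 / (1 + exp(-5)), tolerance = 1e-6)
  expect_equal(invasion_penalty(c(0, 0.5)), c(0, 500))
})

test_that("initialization builds the monolayer-on-fibrin geometry", {
  cfg <- sim_config(mcs_total = 0)
  sim <- initialize_simulation(cfg)
  st <- sim$state
  is_cell <- st$type == 1L
  expect_equal(sum(is_cell), 50)
  expect_true(all(abs(st$area[is_cell] - 200) <= 30))
  expect_equal(sum(st$area), 500 * 150)
  # every fibrin site carries the doubly-bound complex at 1 RU
  fib_sites <- st$type[st$sigma] == 2L
  expect_true(all(sim$fields$F_PLG_LTGF[fib_sites] == 1))
  expect_true(all(sim$fields$F_PLG_LTGF[!fib_sites] == 0))
  expect_true(all(total_fibrin(sim$fields)[fib_sites] == 1))
  # all cells start at the uPAR steady state
  expect_true(all(st$upar[is_cell] ==
                    cfg$kinetics$c / cfg$kinetics$eps_upar))
  # the monolayer plus side patches spans the full width above the fibrin
  mono_row <- max(sim$fibrin_rows) + 1
  row_types <- st$type[st$sigma[mono_row, ]]
  expect_true(all(row_types %in% c(1L, 3L)))

  # plasminogen-depletion initial condition keeps moiety totals at 1
  cfg2 <- sim_config(f_plg_ltgf = 0.4, f_ltgf = 0.6, mcs_total = 0)
  sim2 <- initialize_simulation(cfg2)
  expect_true(all(sim2$fields$F_PLG_LTGF[fib_sites] == 0.4))
  expect_true(all(sim2$fields$F_LTGF[fib_sites] == 0.6))
  expect_true(all(total_fibrin(sim2$fields)[fib_sites] == 1))

  expect_error(initialize_simulation(sim_config(height = 30)), "domain")
  expect_error(sim_config(kinetics = kinetic_params(D_pai = 3)), "stability")
})

test_that("division requires low cell-cell contact and copies uPAR", {
  # an isolated round cell divides with probability P_mitosis per check
  mk <- function() {
    sigma <- matrix(1L, 40, 40)
    sigma[13:27, 13:27] <- 2L
    st <- lattice_state(sigma, c("medium", "cell"),
                        target_area = c(0, 225), upar = c(0, 0.7))
    structure(list(state = st, fields = field_set(40, 40),
                   upar_field = project_upar_field(st),
                   config = small_cfg(), mcs = 10L,
                   events = angiosprout:::empty_events(),
                   initial_fibrin = matrix(FALSE, 40, 40),
                   fibrin_rows = 2:3), class = "sprout_sim")
  }
  set.seed(8)
  n_div <- 0
  for (i in 1:100) {
    sim2 <- maybe_divide(mk())
    n_div <- n_div + nrow(sim2$events)
  }
  # binomial(100, 0.6): 3 SD band
  expect_gt(n_div, 60 - 3 * sqrt(100 * 0.6 * 0.4))
  expect_lt(n_div, 60 + 3 * sqrt(100 * 0.6 * 0.4))

  # daughters partition the parent and inherit its uPAR level
  set.seed(1)
  sim3 <- mk()
  repeat {
    sim4 <- maybe_divide(sim3)
    if (nrow(sim4$events) > 0) break
  }
  st <- sim4$state
  expect_equal(st$area[2] + st$area[3], 225)
  expect_gt(min(st$area[2:3]), 0)
  expect_equal(st$upar[3], 0.7)
  expect_equal(sum(st$sigma == 2L) + sum(st$sigma == 3L), 225)
  expect_identical(st$birth[2:3], c(10L, 10L))

  # a cell fully surrounded by other cells never divides
  sigma <- matrix(2L, 30, 30)
  sigma[1, 1] <- 1L
  sigma[14:17, 14:17] <- 3L
  st5 <- lattice_state(sigma, c("medium", "cell", "cell"),
                       target_area = c(0, 0, 16))
  cr <- angiosprout:::cpp_contact_ratio(st5$sigma, st5$type)
  expect_equal(cr$cell_contact[3] / cr$total[3], 1)
})

test_that("TGF re-dosing fires only on schedule and only on TGF", {
  f <- field_set(6, 4, init = list(PAI = 0.2))
  f2 <- redose_tgf(f, dose = 10, mcs = 1152, period = 1152)
  expect_true(all(f2$TGF == 10))
  expect_identical(f2$PAI, f$PAI)
  f3 <- redose_tgf(f, dose = 10, mcs = 1000, period = 1152)
  expect_identical(f3$TGF, f$TGF)
  f4 <- redose_tgf(f, dose = 0, mcs = 1152, period = 1152)
  expect_identical(f4$TGF, f$TGF)
})

test_that("runs with equal seeds are identical; metrics at MCS 0 are zero", {
  cfg <- small_cfg()
  cfg$mcs_total <- 15
  r1 <- run_simulation(cfg)
  r2 <- run_simulation(cfg)
  expect_identical(r1$sim$state$sigma, r2$sim$state$sigma)
  expect_identical(r1$sim$state$upar, r2$sim$state$upar)
  expect_identical(r1$sim$fields$TGF, r2$sim$fields$TGF)
  expect_identical(r1$metrics, r2$metrics)
  expect_identical(r1$trajectory, r2$trajectory)

  cfg0 <- small_cfg()
  cfg0$mcs_total <- 0
  r0 <- run_simulation(cfg0)
  expect_equal(r0$metrics$angiogenesis_level, 0)
  expect_false(r0$metrics$sprouted)
  expect_equal(r0$metrics$fibrinolysis_pct, 0)
})

test_that("total fibrin never increases anywhere during a run", {
  cfg <- small_cfg()
  set.seed(cfg$seed)
  sim <- initialize_simulation(cfg)
  prev <- total_fibrin(sim$fields)
  for (i in 1:30) {
    sim <- simulation_step(sim)
    cur <- total_fibrin(sim$fields)
    expect_true(all(cur <= prev + 1e-10))
    prev <- cur
  }
})

test_that("without plasmin activation cells stay above dense fibrin", {
  cfg <- small_cfg(kinetics = kinetic_params(k_u1 = 0))
  cfg$mcs_total <- 300
  res <- run_simulation(cfg)
  st <- res$sim$state
  fib_top <- max(res$sim$fibrin_rows)
  below <- st$sigma[1:fib_top, ]
  expect_true(all(st$type[below] != 1L))
  expect_equal(res$metrics$fibrinolysis_pct, 0)
})

test_that("cells remain 8-connected at run checkpoints", {
  cfg <- small_cfg()
  cfg$mcs_total <- 40
  res <- run_simulation(cfg)
  st <- res$sim$state
  for (id in which(st$type == 1L & st$area > 0L)) {
    expect_identical(n_components(st, id), 1L)
  }
})
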