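# Reaction-diffusion system: single-term oracles, conservation structure,
# stencil checks and symmetry.

zero_kinetics <- function(...) {
  args <- list(...)
  base <- lapply(kinetic_params(), function(x) 0)
  do.call(kinetic_params, utils::modifyList(base, args))
}

blank <- function(w = 8, h = 6, init = list()) field_set(w, h, init)
no_cells <- function(w = 8, h = 6) matrix(FALSE, h, w)
no_upar <- function(w = 8, h = 6) matrix(0, h, w)

test_that("total fibrin sums the six fibrin-containing species", {
  f <- blank()
  expect_true(all(total_fibrin(f) == 0))
  f$F_PLG_LTGF[] <- 1
  expect_true(all(total_fibrin(f) == 1))
  f <- blank(init = list(F = 0.2, F_PLG = 0.3))
  expect_true(all(total_fibrin(f) == 0.5))
})

test_that("reaction step with all rates zero is the identity", {
  f <- blank(init = list(F = 0.4, PLG = 0.2, TGF = 0.1, F_PLS = 0.3))
  f2 <- reaction_step(f, no_upar(), no_cells(), zero_kinetics(), dt = 0.1)
  for (nm in names(f)) expect_identical(f2[[nm]], f[[nm]])
})

test_that("single active reactions match their hand-evaluated fluxes", {
  # plasminogen binding only: F and PLG each lose k_f1*dt, F_PLG gains it
  f <- blank(init = list(F = 1, PLG = 1))
  par <- zero_kinetics(k_f1 = 0.2)
  f2 <- reaction_step(f, no_upar(), no_cells(), par, dt = 0.1)
  expect_equal(f2$F[1, 1], 1 - 0.2 * 0.1)
  expect_equal(f2$PLG[1, 1], 1 - 0.2 * 0.1)
  expect_equal(f2$F_PLG[1, 1], 0.2 * 0.1)

  # plasmin activation only (4A): flux F_PLG -> F_PLS is
  # F_PLG * U * k_u1 / (k_m1 + F_PLG) per unit time, at constant U
  f <- blank(init = list(F_PLG = 0.6))
  par <- zero_kinetics(k_u1 = 0.3, k_m1 = 0.5)
  u <- matrix(0.8, 6, 8)  # uniform projected uPAR: NB8 mean is also 0.8
  f2 <- reaction_step(f, u, no_cells(), par, dt = 0.1)
  flux <- 0.6 * 0.8 * 0.3 / (0.5 + 0.6)
  expect_equal(f2$F_PLS[3, 4], flux * 0.1)
  expect_equal(f2$F_PLG[3, 4], 0.6 - flux * 0.1)

  # PAI secretion on cell sites only
  f <- blank()
  par <- zero_kinetics(alpha = 0.05)
  cm <- no_cells(); cm[2, 2] <- TRUE
  f2 <- reaction_step(f, no_upar(), cm, par, dt = 0.1)
  expect_equal(f2$PAI[2, 2], 0.05 * 0.1)
  expect_equal(f2$PAI[1, 1], 0)
})

test_that("diffusion conserves mass and reproduces the 5-point stencil", {
  # uniform field unchanged
  f <- matrix(0.7, 10, 12)
  expect_equal(diffusion_step(f, D = 1, dt = 0.1), f)

  # point release: nu = 0.1 leaves 0.6 at the center, 0.1 at 4-neighbors
  f <- matrix(0, 9, 9); f[5, 5] <- 1
  f2 <- diffusion_step(f, D = 1, dt = 0.1)
  expect_equal(f2[5, 5], 0.6)
  expect_equal(f2[4, 5], 0.1)
  expect_equal(f2[5, 6], 0.1)
  expect_equal(f2[4, 4], 0)  # diagonal not in the stencil

  # closed domain: total mass conserved to machine precision, also from
  # an edge site under the zero-flux boundary
  f <- matrix(0, 7, 7); f[1, 3] <- 2.5
  f2 <- diffusion_step(f, D = 2, dt = 0.12)
  expect_equal(sum(f2), 2.5, tolerance = 1e-13)

  expect_error(diffusion_step(f, D = 3, dt = 0.1), "0.25")
})

test_that("pde step equals reaction-then-diffusion composition", {
  set.seed(21)
  f <- blank(10, 8)
  for (nm in names(f)) f[[nm]][] <- runif(80, 0, 0.5)
  par <- kinetic_params()
  u <- matrix(runif(80, 0, 0.4), 8, 10)
  cm <- matrix(runif(80) < 0.3, 8, 10)
  got <- pde_step(f, u, cm, par, dt = 0.1)
  want <- reaction_step(f, u, cm, par, dt = 0.1)
  for (nm in c("PLG", "LTGF", "TGF", "PAI")) {
    D <- par[[c(PLG = "D_plg", LTGF = "D_ltgf",
                TGF = "D_tgf", PAI = "D_pai")[[nm]]]]
    want[[nm]] <- diffusion_step(want[[nm]], D, 0.1)
  }
  for (nm in names(f)) expect_equal(got[[nm]], want[[nm]])

  # zero rates and zero D: identity
  f0 <- pde_step(f, u, cm, zero_kinetics(), dt = 0.1)
  for (nm in names(f)) expect_identical(f0[[nm]], f[[nm]])
})

test_that("moiety conservation follows the network structure", {
  set.seed(4)
  f <- blank(12, 10)
  # a random mixed state rich in every species
  for (nm in names(f)) f[[nm]][] <- runif(120, 0, 0.3)
  u <- matrix(runif(120, 0, 0.5), 10, 12)
  cm <- matrix(runif(120) < 0.4, 10, 12)

  # all decays and fibrinolysis off: PLG moiety exactly conserved
  par <- kinetic_params(h = 0, eps_plg = 0, eps_ltgf = 0, eps_tgf = 0,
                        eps_pai = 0, eps_fplg = 0, eps_fltgf = 0,
                        eps_fplgl = 0, eps_fpls = 0, eps_fplsl = 0,
                        alpha = 0, k_f3 = 0)
  g <- f
  m0 <- moiety_totals(g)
  for (i in 1:100) g <- pde_step(g, u, cm, par, dt = 0.1)
  m1 <- moiety_totals(g)
  expect_equal(m1[["PLG_moiety"]], m0[["PLG_moiety"]], tolerance = 1e-12)
  expect_equal(m1[["LTGF_moiety"]], m0[["LTGF_moiety"]], tolerance = 1e-12)

  # decays off but fibrinolysis on: LTGF moiety still conserved (release
  # and activation are internal transfers); fibrin moiety decreases
  par$h <- 0.1
  g <- f
  for (i in 1:100) g <- pde_step(g, u, cm, par, dt = 0.1)
  m2 <- moiety_totals(g)
  expect_equal(m2[["LTGF_moiety"]], m0[["LTGF_moiety"]], tolerance = 1e-12)
  expect_lt(m2[["fibrin_moiety"]], m0[["fibrin_moiety"]])
  expect_lt(m2[["PLG_moiety"]], m0[["PLG_moiety"]])
})

test_that("fibrin moiety is non-increasing site-wise under full kinetics", {
  set.seed(9)
  f <- blank(10, 8, init = list(F_PLG_LTGF = 1))
  u <- matrix(runif(80, 0, 0.5), 8, 10)
  cm <- matrix(TRUE, 8, 10)
  par <- kinetic_params()
  prev <- total_fibrin(f)
  for (i in 1:50) {
    f <- pde_step(f, u, cm, par, dt = 0.1)
    cur <- total_fibrin(f)
    expect_true(all(cur <= prev + 1e-12))
    expect_true(all(cur >= 0))
    prev <- cur
  }
})

test_that("deterministic chemistry preserves mirror symmetry", {
  set.seed(31)
  w <- 12; h <- 8
  half <- matrix(runif(h * (w / 2), 0, 0.5), h, w / 2)
  sym <- cbind(half, half[, (w / 2):1])
  f <- blank(w, h)
  f$F_PLG_LTGF <- sym
  f$PAI[] <- 0.1
  u <- cbind(half, half[, (w / 2):1]) * 0.3
  cm <- matrix(FALSE, h, w); cm[5, c(3, w - 2)] <- TRUE  # mirrored cells
  par <- kinetic_params()
  for (i in 1:30) f <- pde_step(f, u, cm, par, dt = 0.1)
  for (nm in names(f)) {
    expect_equal(f[[nm]], f[[nm]][, w:1], tolerance = 1e-12)
  }
})

test_that("halving the time step changes one MCS of chemistry only slightly", {
  # first-order convergence sanity on a fixed scenario
  f <- blank(8, 8, init = list(F_PLG_LTGF = 1))
  u <- matrix(0.4, 8, 8)
  cm <- matrix(TRUE, 8, 8)
  par <- kinetic_params()
  coarse <- f; fine <- f
  for (i in 1:10) coarse <- pde_step(coarse, u, cm, par, dt = 0.1)
  for (i in 1:20) fine <- pde_step(fine, u, cm, par, dt = 0.05)
  for (nm in names(f)) {
    expect_lt(max(abs(coarse[[nm]] - fine[[nm]])), 0.01)
  }
})
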