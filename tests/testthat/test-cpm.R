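params <- cpm_params()

test_that("interfacial energy matches hand-computed and brute-force values", {
  # single identifier: no heterotypic interfaces
  s1 <- lattice_state(matrix(1L, 4, 4), "medium")
  expect_identical(interfacial_energy(s1, params), 0)

  # one cell site next to one medium site on a 1x2 lattice
  s2 <- lattice_state(matrix(c(1L, 2L), nrow = 1), c("cell", "medium"))
  expect_equal(interfacial_energy(s2, params), 30)

  # random lattices against the explicit pair-enumeration oracle
  for (seed in 1:5) {
    st <- random_state(seed = seed)
    expect_equal(interfacial_energy(st, params), brute_interfacial(st, params))
  }
})

test_that("size energy applies only to cells and is quadratic in A - a", {
  st <- two_cell_state(target = 12)  # both cells exactly at target
  expect_identical(size_energy(st, params), 0)

  st$target_area[2] <- 200
  st$area[2] <- 199L
  expect_equal(size_energy(st, params), 100)

  # non-cell identifiers contribute nothing regardless of area mismatch
  st2 <- lattice_state(matrix(c(1L, 1L, 2L, 2L), 2), c("fibrin", "medium"),
                       target_area = c(500, 500))
  expect_identical(size_energy(st2, params), 0)
})

test_that("local delta-H equals global Hamiltonian recomputation", {
  st <- random_state(width = 20, height = 20, n_cells = 5, seed = 42)
  set.seed(7)
  n_checked <- 0
  for (i in 1:1000) {
    y <- sample(2:19, 1); x <- sample(2:19, 1)
    dy <- sample(-1:1, 1); dx <- sample(-1:1, 1)
    if (dy == 0 && dx == 0) next
    src <- c(y, x); tgt <- c(y + dy, x + dx)
    if (st$sigma[src[1], src[2]] == st$sigma[tgt[1], tgt[2]]) {
      expect_identical(delta_hamiltonian(st, src, tgt, params), 0)
      next
    }
    dh_local <- delta_hamiltonian(st, src, tgt, params)
    st2 <- st
    st2$sigma <- st$sigma + 0L
    old <- st2$sigma[tgt[1], tgt[2]]
    new <- st2$sigma[src[1], src[2]]
    st2$sigma[tgt[1], tgt[2]] <- new
    st2$area <- st2$area + 0L
    st2$area[old] <- st2$area[old] - 1L
    st2$area[new] <- st2$area[new] + 1L
    dh_global <- global_hamiltonian(st2, params) - global_hamiltonian(st, params)
    expect_equal(dh_local, dh_global, tolerance = 1e-12)
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 500)
})

test_that("copying medium into a full-size cell costs lambda plus contacts", {
  # isolated 3x3 cell at target area 9 surrounded by medium
  sigma <- matrix(1L, 7, 7)
  sigma[3:5, 3:5] <- 2L
  st <- lattice_state(sigma, c("medium", "cell"), target_area = c(0, 9))
  # extend the cell into the medium site just right of its middle row:
  # size term is lambda * (+1)^2 = 100, interfacial terms computed globally
  dh <- delta_hamiltonian(st, c(4, 5), c(4, 6), params)
  st2 <- st
  st2$sigma <- st$sigma + 0L
  st2$sigma[4, 6] <- 2L
  st2$area <- c(st$area[1] - 1L, st$area[2] + 1L)
  expect_equal(dh, global_hamiltonian(st2, params) - global_hamiltonian(st, params))
  expect_gte(dh, 100)  # includes the lambda (A - a)^2 increment of 100
})

test_that("Boltzmann acceptance follows the fluctuation distribution", {
  expect_identical(acceptance_probability(-5, 0, 100), 1)
  expect_identical(acceptance_probability(0, 0, 100), 1)
  expect_equal(acceptance_probability(100, 0, 100), exp(-1))
  expect_equal(acceptance_probability(50, 150, 100), exp(-2))
  expect_error(acceptance_probability(1, 0, 0), "mu")
})

test_that("empirical acceptance frequency matches exp(-1) within 3 SE", {
  # two abutting cells at target area with zero cell-cell contact energy:
  # flipping one interface site costs only the two size terms, each
  # lambda * (+/-1)^2 = 50, so dH + H0 = 100 exactly with mu = 100.
  J0 <- default_contact_energies()
  J0["cell", "cell"] <- 0
  p50 <- cpm_params(J = J0, lambda_A = 50)
  sigma <- matrix(1L, 8, 10)
  sigma[3:6, 2:4] <- 2L
  sigma[3:6, 5:7] <- 3L
  st <- lattice_state(sigma, c("medium", "cell", "cell"),
                      target_area = c(0, 12, 12))
  dh <- delta_hamiltonian(st, c(4, 4), c(4, 5), p50)
  expect_equal(dh, 100)
  set.seed(123)
  n <- 1e4
  acc <- logical(n)
  for (i in 1:n) {
    acc[i] <- attempt_copy(st, p50, c(4, 4), c(4, 5))$accepted
  }
  p_hat <- mean(acc)
  se <- sqrt(exp(-1) * (1 - exp(-1)) / n)
  expect_lt(abs(p_hat - exp(-1)), 3 * se)
})

test_that("static-type rules silently reject forbidden proposals", {
  sigma <- matrix(1L, 5, 5)
  sigma[3, 3] <- 2L  # cell pixel
  sigma[1, ] <- 3L   # border row
  sigma[5, ] <- 4L   # fibrin row
  st <- lattice_state(sigma, c("medium", "cell", "border", "fibrin"),
                      target_area = c(0, 1, 0, 0))
  # copy into border: rejected, state unchanged
  res <- attempt_copy(st, params, c(2, 3), c(1, 3))
  expect_false(res$evaluated)
  expect_identical(res$state$sigma, st$sigma)
  # copy from border into medium: rejected
  res <- attempt_copy(st, params, c(1, 3), c(2, 3))
  expect_false(res$evaluated)
  # copy from fibrin: rejected (fibrin never extends)
  res <- attempt_copy(st, params, c(5, 3), c(4, 3))
  expect_false(res$evaluated)
})

test_that("strongly favorable proposals are accepted deterministically", {
  # a cell one site short of target next to medium: retracting medium into
  # the cell gap is favorable; engineer dh + H0 < 0 via the size term
  sigma <- matrix(1L, 7, 7)
  sigma[3:5, 3:5] <- 2L
  st <- lattice_state(sigma, c("medium", "cell"), target_area = c(0, 30))
  dh <- delta_hamiltonian(st, c(4, 5), c(4, 6), params)
  expect_lt(dh, 0)
  res <- attempt_copy(st, params, c(4, 5), c(4, 6))
  expect_true(res$accepted)
  expect_identical(res$state$sigma[4, 6], 2L)
  expect_identical(res$state$area, c(39L, 10L))
})

test_that("connectivity penalty keeps cells in one 8-connected piece", {
  # a 2-wide rectangular cell hammered by many MCS never fragments
  sigma <- matrix(1L, 12, 30)
  sigma[6:7, 3:28] <- 2L
  st <- lattice_state(sigma, c("medium", "cell"), target_area = c(0, 52))
  set.seed(99)
  for (i in 1:50) {
    st <- monte_carlo_step(st, params)
    expect_identical(n_components(st, 2L), 1L)
  }
})

test_that("one MCS makes width x height attempts and conserves the partition", {
  st <- random_state(width = 15, height = 9, n_cells = 4, seed = 3)
  set.seed(11)
  st2 <- monte_carlo_step(st, params)
  stats <- attr(st2, "mcs_stats")
  expect_identical(stats$attempts, 15L * 9L)
  expect_identical(sum(st2$area), 15L * 9L)
  expect_identical(st2$area, tabulate(st2$sigma, nbins = length(st2$type)))

  # a lattice of only static types never changes
  sigma <- matrix(1L, 6, 6)
  sigma[4:6, ] <- 2L
  stat <- lattice_state(sigma, c("border", "cell patch"))
  set.seed(5)
  s_after <- monte_carlo_step(stat, params)
  expect_identical(s_after$sigma, sigma)
})
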