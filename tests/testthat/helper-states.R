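# Shared lattice builders for the unit tests.

# A random small lattice populated with a few cells, one fibrin id, medium
# and a border frame; registry types chosen so all type pairs can meet.
random_state <- function(width = 10, height = 10, n_cells = 3, seed = 1) {
  set.seed(seed)
  n_ids <- n_cells + 2L  # medium, fibrin, cells
  sigma <- matrix(sample.int(n_ids, width * height, replace = TRUE),
                  nrow = height, ncol = width)
  type <- c("medium", "fibrin", rep("cell", n_cells))
  lattice_state(sigma, type, target_area = c(0, 0, rep(20, n_cells)),
                upar = rep(0, n_ids))
}

# Two cells side by side in medium on a small lattice; areas at target.
two_cell_state <- function(target = 12) {
  sigma <- matrix(1L, nrow = 8, ncol = 10)
  sigma[3:6, 2:4] <- 2L   # cell A, 12 sites
  sigma[3:6, 6:8] <- 3L   # cell B, 12 sites
  lattice_state(sigma, c("medium", "cell", "cell"),
                target_area = c(0, target, target))
}

# Global-recompute oracle for the Hamiltonian.
global_hamiltonian <- function(state, params) {
  interfacial_energy(state, params) + size_energy(state, params)
}

# Brute-force interfacial energy: explicit double loop over all 8-neighbor
# pairs, counting each unordered pair once.
brute_interfacial <- function(state, params) {
  sigma <- state$sigma
  H <- nrow(sigma); W <- ncol(sigma)
  e <- 0
  for (y in 1:H) for (x in 1:W) {
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      yy <- y + dy; xx <- x + dx
      if (yy < 1 || yy > H || xx < 1 || xx > W) next
      if (sigma[yy, xx] != sigma[y, x])
        e <- e + params$J[state$type[sigma[y, x]], state$type[sigma[yy, xx]]]
    }
  }
  e / 2
}
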