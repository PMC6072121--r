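# Cellular Potts lattice, Hamiltonian terms and the copy-attempt kernel.

# integer type codes used on the lattice and in compiled code
TYPE_CODES <- c(cell = 1L, fibrin = 2L, "cell patch" = 3L,
                border = 4L, medium = 5L)

#' Generalized-cell type names
#'
#' @return Character vector of the five generalized-cell types.
#' @export
cpm_types <- function() names(TYPE_CODES)

type_code <- function(x) {
  if (is.numeric(x)) return(as.integer(x))
  code <- TYPE_CODES[match(x, names(TYPE_CODES))]
  if (anyNA(code)) stop("unknown generalized-cell type: ",
                        paste(setdiff(x, names(TYPE_CODES)), collapse = ", "))
  unname(code)
}

#' Default interfacial-energy table
#'
#' Symmetric 5x5 matrix of contact energies J(tau, tau') between the
#' generalized-cell types, with the default endothelial-cell/fibrin values:
#' J(cell, cell) = 15, J(cell, medium) = 30, J(cell, fibrin) = 75,
#' J(fibrin, medium) = 120 and J(cell, border) = 1e6 (cells are repelled by
#' the domain boundary).  The static cell patch adheres like a regular
#' cell.  Interfaces between sites of the same identifier carry no energy,
#' so entries only matter for type pairs that meet across an identifier
#' boundary.
#'
#' @return Numeric matrix with dimnames over [cpm_types()].
#' @export
default_contact_energies <- function() {
  J <- matrix(0, 5, 5, dimnames = list(cpm_types(), cpm_types()))
  set <- function(a, b, v) {
    J[a, b] <<- v
    J[b, a] <<- v
  }
  set("cell", "cell", 15)
  set("cell", "medium", 30)
  set("cell", "fibrin", 75)
  set("cell", "border", 1e6)
  set("fibrin", "medium", 120)
  # the immobile side patches have the same adhesion parameters as cells
  set("cell patch", "cell", 15)
  set("cell patch", "medium", 30)
  set("cell patch", "fibrin", 75)
  J
}

#' Cellular Potts model parameters
#'
#' @param J Symmetric interfacial-energy table over the five generalized
#'   cell types (see [default_contact_energies()]).
#' @param lambda_A Inverse cell compressibility (Lagrange multiplier of the
#'   area constraint); applies to type-cell identifiers only.
#' @param mu Amplitude of active random membrane fluctuations (the CPM
#'   "cellular temperature"); must be positive.
#' @param h_connectivity Energy penalty added to copy attempts that would
#'   fragment the retracting cell into disconnected patches.
#' @return Object of class `cpm_params`.
#' @export
cpm_params <- function(J = default_contact_energies(), lambda_A = 100,
                       mu = 100, h_connectivity = 1e9) {
  stopifnot(is.matrix(J), nrow(J) == 5, ncol(J) == 5)
  if (!isTRUE(all.equal(J, t(J))))
    stop("interfacial-energy table J must be symmetric")
  if (mu <= 0) stop("membrane-fluctuation amplitude mu must be positive")
  if (lambda_A < 0) stop("lambda_A must be non-negative")
  structure(list(J = J, lambda_A = lambda_A, mu = mu,
                 h_connectivity = h_connectivity),
            class = "cpm_params")
}

#' Construct a lattice state
#'
#' A lattice state is the Potts grid of generalized-cell identifiers plus
#' the per-identifier registry (type, target area, actual area, uPAR
#' level).  Actual areas are derived from the grid; identifiers are
#' 1-based and every site's identifier must exist in the registry.
#'
#' @param sigma Integer matrix of identifiers; rows index the vertical
#'   coordinate with row 1 at the bottom of the domain.
#' @param type Per-identifier type, as names from [cpm_types()] or integer
#'   codes.
#' @param target_area Per-identifier target area in sites (only used for
#'   type-cell identifiers).
#' @param upar Per-identifier uPAR level in relative units.
#' @param birth Per-identifier birth time in MCS (for lineage statistics).
#' @return Object of class `lattice_state`.
#' @export
lattice_state <- function(sigma, type, target_area = rep(0, length(type)),
                          upar = rep(0, length(type)),
                          birth = rep(0L, length(type))) {
  storage.mode(sigma) <- "integer"
  code <- type_code(type)
  n <- length(code)
  if (min(sigma) < 1L || max(sigma) > n)
    stop("every site identifier must exist in the registry")
  area <- tabulate(sigma, nbins = n)
  structure(list(sigma = sigma, type = code,
                 target_area = as.numeric(rep_len(target_area, n)),
                 area = as.integer(area),
                 upar = as.numeric(rep_len(upar, n)),
                 birth = as.integer(rep_len(birth, n))),
            class = "lattice_state")
}

copy_state <- function(state) {
  state$sigma <- state$sigma + 0L
  state$area <- state$area + 0L
  state
}

#' Total interfacial energy of a lattice
#'
#' Sum of J(tau, tau') over all 8-adjacent site pairs carrying different
#' identifiers.
#'
#' @param state A [lattice_state()].
#' @param params A [cpm_params()].
#' @return Dimensionless energy.
#' @export
interfacial_energy <- function(state, params) {
  cpp_interfacial_energy(state$sigma, state$type, params$J)
}

#' Area-constraint energy of a lattice
#'
#' `sum(lambda_A * (A - a)^2)` over type-cell identifiers; fibrin, medium
#' and static identifiers contribute nothing.
#'
#' @inheritParams interfacial_energy
#' @return Dimensionless energy.
#' @export
size_energy <- function(state, params) {
  cpp_size_energy(state$type, state$area, state$target_area, params$lambda_A)
}

#' Hamiltonian change of a single copy attempt
#'
#' Local, incremental computation of the change in
#' `interfacial_energy() + size_energy()` when the identifier at
#' `source` is copied into the 8-neighboring site `target`.
#'
#' @inheritParams interfacial_energy
#' @param source,target Sites as `c(row, col)` (1-based).
#' @return Dimensionless energy change.
#' @export
delta_hamiltonian <- function(state, source, target, params) {
  cpp_delta_hamiltonian(state$sigma, state$type, state$area,
                        state$target_area, params$J, params$lambda_A,
                        source[1], source[2], target[1], target[2])
}

#' Boltzmann acceptance probability of a copy attempt
#'
#' A proposal with `dH + H0 < 0` is always accepted; otherwise it is
#' accepted with probability `exp(-(dH + H0) / mu)`.
#'
#' @param dH Hamiltonian change of the proposal.
#' @param H0 Dissipative-energy offset (fibrin obstruction, connectivity
#'   penalty).
#' @param mu Membrane-fluctuation amplitude; must be positive.
#' @return Probability in `[0, 1]`, vectorized over `dH`/`H0`.
#' @export
acceptance_probability <- function(dH, H0 = 0, mu = 100) {
  if (any(mu <= 0)) stop("membrane-fluctuation amplitude mu must be positive")
  pmin(1, exp(-(dH + H0) / mu))
}

#' Perform one copy attempt at a chosen site pair
#'
#' Applies the static-type rules (only cells and medium may move; fibrin
#' may only be invaded; cell patch and border never change), adds the
#' fibrin-obstruction and connectivity penalties to `H0`, and accepts with
#' the Boltzmann probability.  Uses R's RNG stream.
#'
#' @inheritParams delta_hamiltonian
#' @param fibrin_total Optional matrix of total fibrin concentration (see
#'   [total_fibrin()]); when given, copies into fibrin-type sites incur the
#'   invasion penalty of [invasion_penalty()].
#' @param invasion An [invasion_params()].
#' @return List with the updated `state` and flags `evaluated` (proposal
#'   passed the type rules) and `accepted`.
#' @export
attempt_copy <- function(state, params, source, target,
                         fibrin_total = NULL,
                         invasion = invasion_params()) {
  state <- copy_state(state)
  res <- cpp_attempt_copy_at(state$sigma, state$type, state$area,
                             state$target_area, params$J, params$lambda_A,
                             params$mu, params$h_connectivity, fibrin_total,
                             invasion$p, invasion$E, invasion$m,
                             invasion$theta_fibrin,
                             source[1], source[2], target[1], target[2])
  list(state = state, evaluated = res$evaluated, accepted = res$accepted)
}

#' Perform one Monte Carlo step
#'
#' Executes as many copy attempts as there are lattice sites, each picking
#' a uniformly random site and a uniformly random 8-neighbor.  Proposals
#' violating the static-type rules are silent rejections; accepted copies
#' update the identifier grid and the area bookkeeping.
#'
#' @inheritParams attempt_copy
#' @return The updated `lattice_state`, with an attribute `mcs_stats`
#'   (attempts, evaluated, accepted counts).
#' @export
monte_carlo_step <- function(state, params, fibrin_total = NULL,
                             invasion = invasion_params()) {
  state <- copy_state(state)
  stats <- cpp_monte_carlo_step(state$sigma, state$type, state$area,
                                state$target_area, params$J,
                                params$lambda_A, params$mu,
                                params$h_connectivity, fibrin_total,
                                invasion$p, invasion$E, invasion$m,
                                invasion$theta_fibrin)
  attr(state, "mcs_stats") <- stats
  state
}

#' Number of 8-connected components of an identifier
#'
#' Full breadth-first audit; used to verify that the connectivity penalty
#' keeps cells in one piece.
#'
#' @inheritParams interfacial_energy
#' @param id Identifier to audit.
#' @return Integer component count.
#' @export
n_components <- function(state, id) cpp_n_components(state$sigma, id)
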