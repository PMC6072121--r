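# Per-cell membrane-uPAR dynamics and lattice projection.

#' Neighborhood-averaged uPAR at a site
#'
#' Arithmetic mean of the projected uPAR field over a site and its
#' existing 8-neighbors (9 sites in the interior); this is the uPAR level
#' seen by the plasmin-activation reaction.
#'
#' @param upar_field Projected uPAR field matrix.
#' @param site Site as `c(row, col)` (1-based).
#' @return uPAR level in RU.
#' @export
neighborhood_upar <- function(upar_field, site) {
  rows <- intersect(site[1] + (-1:1), seq_len(nrow(upar_field)))
  cols <- intersect(site[2] + (-1:1), seq_len(ncol(upar_field)))
  mean(upar_field[rows, cols])
}

#' Rate of change of per-cell uPAR
#'
#' For each type-cell identifier: first-order decay, internalization upon
#' PAI-1 binding summed over all occupied sites, constant basal production
#' `c`, and TGFbeta1-induced production saturating in the squared sum of
#' TGFbeta1 over the cell's boundary sites:
#' `-eps_upar * u - u * k_f3 * sum(PAI over C(s)) + c +
#'  k_u3 * T^2 / (k_m3 + T^2)` with `T = sum(TGF over P(s))`.
#'
#' @param state A [lattice_state()].
#' @param fields A [field_set()] supplying the TGF and PAI fields.
#' @param params A [kinetic_params()].
#' @return Numeric vector of rates (RU/MCS) indexed by identifier;
#'   non-cell identifiers get `NA`.
#' @export
upar_rhs <- function(state, fields, params) {
  sums <- cpp_cell_sums(state$sigma, state$type, fields$TGF, fields$PAI)
  rate <- upar_rhs_vec(state$upar, sums$pai_sum, sums$tgf_sum, params)
  rate[state$type != TYPE_CODES[["cell"]]] <- NA_real_
  rate
}

upar_rhs_vec <- function(upar, pai_sum, tgf_sum, params) {
  -params$eps_upar * upar - upar * params$k_f3 * pai_sum + params$c +
    params$k_u3 * tgf_sum^2 / (params$k_m3 + tgf_sum^2)
}

#' One Euler step of the per-cell uPAR equations
#'
#' Updates every cell's uPAR level with one explicit Euler step of
#' [upar_rhs()] at the frozen CPM and field state (operator splitting).
#' uPAR is floored at zero with a warning when the step would drive it
#' negative.
#'
#' @inheritParams upar_rhs
#' @param dt Time step in MCS (default one MCS = 150 s).
#' @return The `lattice_state` with updated uPAR levels.
#' @export
ode_step <- function(state, fields, params, dt = 1) {
  sums <- cpp_cell_sums(state$sigma, state$type, fields$TGF, fields$PAI)
  rate <- upar_rhs_vec(state$upar, sums$pai_sum, sums$tgf_sum, params)
  is_cell <- state$type == TYPE_CODES[["cell"]]
  new_upar <- state$upar
  new_upar[is_cell] <- state$upar[is_cell] + dt * rate[is_cell]
  if (any(!is.finite(new_upar[is_cell])))
    stop("non-finite uPAR level after ODE step")
  if (any(new_upar[is_cell] < 0)) {
    warning("uPAR driven below zero; floored at 0")
    new_upar[is_cell] <- pmax(new_upar[is_cell], 0)
  }
  state$upar <- new_upar
  state
}

#' Project per-cell uPAR onto the lattice
#'
#' Every site occupied by a cell carries that cell's uPAR level; all other
#' sites carry zero.  The projection is refreshed after each ODE step so
#' the uPAR concentration moves along with the cell.
#'
#' @inheritParams upar_rhs
#' @return Numeric matrix of the same dimensions as the lattice.
#' @export
project_upar_field <- function(state) {
  out <- matrix(0, nrow = nrow(state$sigma), ncol = ncol(state$sigma))
  cpp_project_upar(state$sigma, state$type, state$upar, out)
  out
}

#' Logical mask of cell-occupied sites
#'
#' @inheritParams upar_rhs
#' @return Logical matrix, `TRUE` where the site belongs to a type-cell
#'   identifier.
#' @export
cell_mask <- function(state) {
  matrix(state$type[state$sigma] == TYPE_CODES[["cell"]],
         nrow = nrow(state$sigma))
}
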