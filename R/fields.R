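# The ten-species plasminogen-plasmin-TGFbeta1 reaction-diffusion system.

FIELD_NAMES <- c("F", "PLG", "LTGF", "TGF", "PAI",
                 "F_PLG", "F_LTGF", "F_PLG_LTGF", "F_PLS", "F_PLS_LTGF")
FIBRIN_SPECIES <- c("F", "F_PLG", "F_LTGF", "F_PLG_LTGF", "F_PLS", "F_PLS_LTGF")
DIFFUSING <- c(PLG = "D_plg", LTGF = "D_ltgf", TGF = "D_tgf", PAI = "D_pai")

#' Construct the set of concentration fields
#'
#' Ten co-registered scalar fields on the CPM grid, in relative units (RU):
#' free fibrin `F`, free plasminogen `PLG`, free latent TGFbeta1 `LTGF`,
#' active TGFbeta1 `TGF`, PAI-1 `PAI`, and the fibrin-bound complexes
#' `F_PLG`, `F_LTGF`, `F_PLG_LTGF` (doubly loaded), `F_PLS` and
#' `F_PLS_LTGF` (plasmin forms).  Fibrin-bound species are immobile; only
#' the free species diffuse.
#'
#' @param width,height Lattice dimensions in sites.
#' @param init Named list of initial values; each entry may be a scalar or
#'   a matrix.  Unnamed species start at zero.
#' @return Named list of numeric matrices (class `field_set`).
#' @export
field_set <- function(width, height, init = list()) {
  unknown <- setdiff(names(init), FIELD_NAMES)
  if (length(unknown))
    stop("unknown species: ", paste(unknown, collapse = ", "))
  fields <- lapply(FIELD_NAMES, function(nm) {
    v <- init[[nm]]
    if (is.null(v)) v <- 0
    matrix(v, nrow = height, ncol = width)
  })
  names(fields) <- FIELD_NAMES
  structure(fields, class = "field_set")
}

#' Kinetic, diffusion and decay parameters
#'
#' All rates are in relative units per Monte Carlo step (1 MCS is about
#' 2.5 minutes of real time) and diffusion coefficients in lattice sites
#' squared per MCS.  The defaults are the package's calibrated qualitative
#' set; the anchored values are the basal uPAR production rate `c`
#' (swept over 0.001-0.005 RU/MCS in the experiments), the PAI-1 decay
#' rate `eps_pai = 0.01` per MCS and the uPAR decay rate
#' `eps_upar = 0.0095` per MCS.
#'
#' @param k_f1,k_r1 Forward/reverse plasminogen-fibrin binding rates (the
#'   same constants govern binding to fibrin already carrying latent
#'   TGFbeta1, as binding is non-competitive).
#' @param k_f2,k_r2 Forward/reverse latent-TGFbeta1-fibrin binding rates.
#' @param k_u1,k_m1 Michaelis-Menten constants of uPAR-mediated conversion
#'   of fibrin-bound plasminogen to plasmin.
#' @param k_u2,k_m2 Michaelis-Menten constants of plasmin-mediated release
#'   and activation of fibrin-bound latent TGFbeta1.
#' @param h,d Maximal rate and half-saturation constant of the
#'   fibrinolysis Hill term `h * X^2 / (d + X^2)` acting on the two
#'   plasmin-bound fibrin forms.
#' @param k_f3 Rate of PAI-1 binding to uPAR-bound uPA (internalization of
#'   the complex depletes both PAI-1 and uPAR).
#' @param alpha PAI-1 secretion rate at every cell-occupied site.
#' @param c Basal (TGFbeta1-independent) uPAR production rate per cell.
#' @param k_u3,k_m3 Maximal rate and half-saturation constant (on the
#'   squared perimeter TGFbeta1 sum) of TGFbeta1-induced uPAR production.
#' @param eps_plg,eps_ltgf,eps_tgf,eps_pai,eps_upar First-order decay
#'   rates of the free species and of uPAR.
#' @param eps_fplg,eps_fltgf,eps_fplgl,eps_fpls,eps_fplsl First-order
#'   decay rates of the fibrin-bound complexes (free fibrin itself does
#'   not decay).
#' @param D_plg,D_ltgf,D_tgf,D_pai Diffusion coefficients of the four
#'   mobile species.
#' @return Named list of class `kinetic_params`.
#' @export
kinetic_params <- function(k_f1 = 0.1, k_r1 = 0.01,
                           k_f2 = 0.1, k_r2 = 0.01,
                           k_u1 = 7.5e-3, k_m1 = 0.5,
                           k_u2 = 0.02, k_m2 = 0.25,
                           h = 0.022, d = 0.05,
                           k_f3 = 0.004, alpha = 0.001,
                           c = 0.005, k_u3 = 0.8, k_m3 = 0.004,
                           eps_plg = 0.001, eps_ltgf = 0.001,
                           eps_tgf = 0.1, eps_pai = 0.01,
                           eps_upar = 0.0095,
                           eps_fplg = 1e-5, eps_fltgf = 1e-5,
                           eps_fplgl = 1e-5, eps_fpls = 0.03,
                           eps_fplsl = 0.03,
                           D_plg = 2, D_ltgf = 2, D_tgf = 0.5, D_pai = 2) {
  par <- as.list(environment())
  bad <- names(par)[vapply(par, function(v) !is.numeric(v) || v < 0, TRUE)]
  if (length(bad))
    stop("kinetic parameters must be non-negative numbers: ",
         paste(bad, collapse = ", "))
  structure(par, class = "kinetic_params")
}

#' Total fibrin concentration
#'
#' Sum of all six fibrin-containing species at every site.  With no fibrin
#' sources in the model this stays in `[0, 1]` when initialized at 1.
#'
#' @param fields A [field_set()].
#' @return Numeric matrix.
#' @export
total_fibrin <- function(fields) {
  Reduce(`+`, fields[FIBRIN_SPECIES])
}

#' One forward-Euler reaction update (no transport)
#'
#' Applies every reaction term of the network: reversible plasminogen and
#' latent-TGFbeta1 binding to fibrin, uPAR-mediated plasmin activation,
#' plasmin-mediated TGFbeta1 release, the fibrinolysis Hill terms (the
#' doubly-loaded form also sourcing free latent TGFbeta1), PAI-1 secretion
#' on cell sites and its uPAR-mediated internalization, and all
#' first-order decays.  The uPAR level driving plasmin activation at a
#' site is the 9-site neighborhood mean of the projected uPAR field.
#' No clipping is applied; a warning is raised if any concentration drops
#' below `-1e-9`, signalling a too-large time step.
#'
#' @inheritParams total_fibrin
#' @param upar_field Projected per-cell uPAR field (see
#'   [project_upar_field()]).
#' @param cell_mask Logical matrix marking sites occupied by type-cell
#'   identifiers (the PAI-1 secretion locus).
#' @param params A [kinetic_params()].
#' @param dt Time step in MCS.
#' @return The updated `field_set`.
#' @export
reaction_step <- function(fields, upar_field, cell_mask, params, dt) {
  fields <- duplicate_fields(fields)
  min_val <- cpp_reaction_step(fields$F, fields$PLG, fields$LTGF, fields$TGF,
                               fields$PAI, fields$F_PLG, fields$F_LTGF,
                               fields$F_PLG_LTGF, fields$F_PLS,
                               fields$F_PLS_LTGF, upar_field, cell_mask,
                               params, dt)
  if (min_val < -1e-9)
    warning("concentration fell below zero (", signif(min_val, 3),
            "); the reaction time step is likely too large")
  fields
}

#' One explicit diffusion update of a single field
#'
#' Five-point Laplacian with zero-flux (reflecting) boundaries; conserves
#' total mass on the closed domain.  The lattice diffusion number
#' `D * dt / dx^2` must stay below 0.25 for stability.
#'
#' @param field Numeric matrix.
#' @param D Diffusion coefficient.
#' @param dt Time step.
#' @param dx Lattice spacing (1 site = 2 um).
#' @return The updated matrix.
#' @export
diffusion_step <- function(field, D, dt, dx = 1) {
  field <- field + 0
  cpp_diffusion_step(field, D, dt, dx)
  field
}

#' One combined reaction-diffusion step
#'
#' [reaction_step()] followed by [diffusion_step()] for each of the four
#' mobile species (PLG, LTGF, TGF, PAI); fibrin-bound species are
#' structurally immobile.  Ten such substeps of `dt = 0.1` MCS (15 s)
#' advance the chemistry by one MCS.
#'
#' @inheritParams reaction_step
#' @inheritParams diffusion_step
#' @return The updated `field_set`.
#' @export
pde_step <- function(fields, upar_field, cell_mask, params, dt, dx = 1) {
  fields <- reaction_step(fields, upar_field, cell_mask, params, dt)
  for (nm in names(DIFFUSING)) {
    cpp_diffusion_step(fields[[nm]], params[[DIFFUSING[[nm]]]], dt, dx)
  }
  fields
}

#' Conserved-moiety totals
#'
#' Diagnostic sums over the reaction network: the plasminogen moiety
#' (free + all bound and converted forms), the latent-TGFbeta1 moiety
#' (free, bound and activated forms) and total fibrin.  With all decays
#' off, the PLG moiety is conserved when fibrinolysis is off and the LTGF
#' moiety is conserved unconditionally (release and activation are
#' internal transfers); the fibrin moiety never increases.
#'
#' @inheritParams total_fibrin
#' @return Named numeric vector with elements `PLG_moiety`, `LTGF_moiety`
#'   and `fibrin_moiety`.
#' @export
moiety_totals <- function(fields) {
  c(PLG_moiety = sum(fields$PLG) + sum(fields$F_PLG) +
      sum(fields$F_PLG_LTGF) + sum(fields$F_PLS) + sum(fields$F_PLS_LTGF),
    LTGF_moiety = sum(fields$LTGF) + sum(fields$F_LTGF) +
      sum(fields$F_PLG_LTGF) + sum(fields$F_PLS_LTGF) + sum(fields$TGF),
    fibrin_moiety = sum(total_fibrin(fields)))
}

duplicate_fields <- function(fields) {
  for (nm in names(fields)) fields[[nm]] <- fields[[nm]] + 0
  fields
}
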