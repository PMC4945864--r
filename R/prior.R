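#' Uniform draw on the unit simplex (flat Dirichlet)
#' @keywords internal
rsimplex <- function(n) {
  if (n == 1L) return(1)
  g <- stats::rexp(n)
  g / sum(g)
}

#' Sample the auxiliary variables of one reaction
#'
#' Draws the bounded auxiliary variables that implicitly parameterize a
#' reaction's kinetics at the reference point: enzyme intermediate abundances
#' (uniform on the simplex), microscopic reversibilities (obtained by
#' allocating the reference driving force dG_r/RT across the steps of each
#' catalytic route with flat simplex weights, so the route product constraint
#' holds by construction), branching fractions (uniform on the simplex over
#' routes) and, for allosteric enzymes, the reference R-state fraction and
#' effector saturations (uniform in (0,1)).
#'
#' Steps shared between routes receive their reversibility from the first
#' route that visits them; later routes allocate the residual driving force
#' across their exclusive steps (thermodynamic cycle closure guarantees the
#' residual is a valid driving force for well-formed branch structures).
#'
#' @param mech a [reaction_mechanism()], oriented along the net flux.
#' @param dG_r Gibbs free energy of the reaction at reference (kJ/mol),
#'   signed for the mechanism's forward direction (must be negative).
#' @param RT kJ/mol.
#' @return list with elements `abundances`, `reversibilities`,
#'   `branch_fractions`, `allosteric` (or NULL).
#' @export
sample_auxiliary <- function(mech, dG_r, RT = 2.5787) {
  if (!is.finite(dG_r)) stop("dG_r must be finite")
  if (dG_r == 0) stop("no thermodynamic driving force (dG_r = 0) for flux-carrying reaction '",
                      mech$name, "'")
  if (dG_r > 0) stop("dG_r must be negative along the net flux direction of '",
                     mech$name, "' (got ", dG_r, ")")
  total <- dG_r / RT                      # negative log driving force
  ab <- rsimplex(length(mech$states))
  names(ab) <- mech$states
  lnr <- rep(NA_real_, length(mech$steps))
  for (route in mech$routes) {
    free <- route[is.na(lnr[route])]
    if (!length(free)) {
      if (abs(sum(lnr[route]) - total) > 1e-9 * max(1, abs(total))) {
        stop("inconsistent shared-step reversibilities in mechanism '",
             mech$name, "'")
      }
      next
    }
    residual <- total - sum(lnr[route][!is.na(lnr[route])], na.rm = TRUE)
    if (residual >= 0) {
      stop("branch structure of mechanism '", mech$name,
           "' leaves no driving force for an exclusive segment")
    }
    lnr[free] <- rsimplex(length(free)) * residual
  }
  if (anyNA(lnr)) stop("mechanism '", mech$name, "' has steps on no route")
  allo <- NULL
  if (!is.null(mech$allosteric)) {
    eff <- c(mech$allosteric$activators, mech$allosteric$inhibitors)
    allo <- list(rho = stats::runif(1),
                 saturations = stats::setNames(stats::runif(length(eff)), eff))
  }
  list(abundances = ab, reversibilities = exp(lnr),
       branch_fractions = rsimplex(length(mech$routes)),
       allosteric = allo)
}

#' Assemble scaled elementary rate constants from auxiliary variables
#'
#' Uses the elementary-level normalization: every step on a route carrying
#' net flux v_route = branch_fraction * |v_ref| has one-way forward flux
#' v_step/(1 - r) and one-way reverse flux v_step r/(1 - r) at the reference
#' (v_step sums route fluxes over routes sharing the step). Scaled rate
#' constants follow by dividing by the source-state abundance; reference
#' concentrations are 1 in normalized units.
#'
#' @param mech oriented mechanism.
#' @param aux result of [sample_auxiliary()].
#' @param v_ref_mag positive net reference flux magnitude.
#' @return list with numeric vectors `kf`, `kr` (one per step).
#' @export
assemble_rate_constants <- function(mech, aux, v_ref_mag) {
  if (v_ref_mag <= 0) stop("v_ref_mag must be positive")
  r <- aux$reversibilities
  if (any(r >= 1)) stop("step reversibility >= 1 on a forward-driven route of '",
                        mech$name, "'")
  step_flux <- numeric(length(mech$steps))
  for (k in seq_along(mech$routes)) {
    step_flux[mech$routes[[k]]] <- step_flux[mech$routes[[k]]] +
      aux$branch_fractions[k] * v_ref_mag
  }
  fwd <- step_flux / (1 - r)
  rev <- step_flux * r / (1 - r)
  from <- vapply(mech$steps, function(s) s$from, character(1))
  to <- vapply(mech$steps, function(s) s$to, character(1))
  list(kf = fwd / aux$abundances[from],
       kr = rev / aux$abundances[to])
}

#' Assemble the MWC allosteric constants from auxiliary variables
#'
#' Back-calculates the allosteric constant L and the effector constants
#' K_eff from the sampled reference R-state fraction rho and effector
#' saturations s (exclusive binding: inhibitors bind the T state, activators
#' the R state). With normalized reference concentrations,
#' K_eff = (1 - s)/s and L = (1 - rho)/rho * (t_act/t_inh)^n where
#' t_act, t_inh are the reference activator/inhibitor occupancy terms.
#'
#' @param mech mechanism with an allosteric specification.
#' @param aux result of [sample_auxiliary()].
#' @return list with `L`, `K_act`, `K_inh`, `n`, `Q_ref`.
#' @export
assemble_allosteric <- function(mech, aux) {
  al <- mech$allosteric
  if (is.null(al)) stop("mechanism '", mech$name, "' has no allosteric spec")
  s <- aux$allosteric$saturations
  rho <- aux$allosteric$rho
  if (any(s <= 0 | s >= 1) || rho <= 0 || rho >= 1) {
    stop("degenerate allosteric auxiliary sample (saturation or rho at 0/1)")
  }
  K <- (1 - s) / s
  K_act <- K[al$activators]
  K_inh <- K[al$inhibitors]
  t_act <- 1 + sum(1 / K_act)
  t_inh <- 1 + sum(1 / K_inh)
  L <- (1 - rho) / rho * (t_act / t_inh)^al$n
  Q_ref <- (1 - rho) / rho
  list(L = L, K_act = K_act, K_inh = K_inh, n = al$n, Q_ref = Q_ref)
}

#' Sample one full kinetic particle from the feasible prior
#'
#' Draws auxiliary variables for every reaction of the network and assembles
#' the scaled elementary rate constants plus MWC allosteric constants. Every
#' particle reproduces the reference flux distribution exactly when evaluated
#' at the reference state (anchoring identity) and is Haldane-consistent with
#' the reference Gibbs free energies.
#'
#' @param net a `metabolic_network` with mechanisms for all reactions.
#' @param ref a [reference_state()].
#' @param seed optional integer seed (draw is deterministic given the seed).
#' @param structure_index integer tag identifying the model structure.
#' @param plan optional precompiled [rate_plan()] (avoids recompilation in
#'   tight sampling loops).
#' @return object of class `kinetic_particle`.
#' @export
sample_prior_particle <- function(net, ref, seed = NULL, structure_index = 0L,
                                  plan = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(plan)) plan <- rate_plan(net, ref)
  rxs <- vector("list", length(net$reactions))
  names(rxs) <- net$reactions
  for (rx in net$reactions) {
    mech <- plan$oriented[[rx]]
    dG_eff <- ref$dG_r[[rx]] * plan$orientation[[rx]]
    aux <- sample_auxiliary(mech, dG_eff, RT = ref$RT)
    kc <- assemble_rate_constants(mech, aux, abs(ref$v_ref[[rx]]))
    allo <- if (!is.null(mech$allosteric)) assemble_allosteric(mech, aux) else NULL
    rxs[[rx]] <- list(kf = unname(kc$kf), kr = unname(kc$kr),
                      allosteric = allo, aux = aux)
  }
  structure(list(reactions = rxs, structure_index = as.integer(structure_index)),
            class = "kinetic_particle")
}

#' Flatten a particle into a named parameter vector
#'
#' Scaled forward/backward constants per elementary step, then L and the
#' effector constants for allosteric reactions.
#' @param particle a `kinetic_particle`.
#' @export
particle_params <- function(particle) {
  out <- numeric(0)
  for (rx in names(particle$reactions)) {
    p <- particle$reactions[[rx]]
    ns <- length(p$kf)
    v <- c(rbind(p$kf, p$kr))
    names(v) <- as.vector(rbind(paste0(rx, ".s", seq_len(ns), ".kf"),
                                paste0(rx, ".s", seq_len(ns), ".kr")))
    out <- c(out, v)
    if (!is.null(p$allosteric)) {
      al <- p$allosteric
      keff <- c(al$K_act, al$K_inh)
      v2 <- stats::setNames(al$L, paste0(rx, ".L"))
      if (length(keff)) {
        v2 <- c(v2, stats::setNames(keff, paste0(rx, ".Keff.", names(keff))))
      }
      out <- c(out, v2)
    }
  }
  out
}

#' Write / read particle ensembles as delimited text
#'
#' One row per particle, columns named after every parameter (plus the
#' structure index).
#' @param particles list of `kinetic_particle`.
#' @param file path to a TSV file.
#' @export
write_particles <- function(particles, file) {
  mat <- do.call(rbind, lapply(particles, particle_params))
  df <- data.frame(structure_index =
                     vapply(particles, function(p) p$structure_index, integer(1)),
                   mat, check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_particles
#' @export
read_particle_params <- function(file) {
  utils::read.delim(file, check.names = FALSE)
}

#' Canonical kinetic parameters of a three-step uni-uni mechanism
#'
#' King-Altman closed forms for E+S = ES = EP = E+P: turnover numbers and
#' Michaelis constants in terms of the six elementary constants. Used to
#' compare sampled parameterizations with canonical literature parameters
#' (elementary constants themselves are not identifiable; these combinations
#' are).
#' @param kf,kr length-3 forward/backward elementary constants
#'   (bind, catalytic, release).
#' @return named vector kcat_f, Km_S, kcat_r, Km_P.
#' @export
canonical_uni_uni <- function(kf, kr) {
  k1 <- kf[1]; k2 <- kf[2]; k3 <- kf[3]
  km1 <- kr[1]; km2 <- kr[2]; km3 <- kr[3]
  c(kcat_f = k2 * k3 / (k2 + km2 + k3),
    Km_S = (km1 * km2 + km1 * k3 + k2 * k3) / (k1 * (k2 + km2 + k3)),
    kcat_r = km1 * km2 / (km1 + k2 + km2),
    Km_P = (km1 * km2 + km1 * k3 + k2 * k3) / (km3 * (km1 + k2 + km2)))
}
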