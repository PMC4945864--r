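#' Metabolic network with boundary fluxes and moiety pools
#'
#' Container for the stoichiometry of a small metabolic network. Columns of
#' `S` are the kinetically modelled reactions; boundary fluxes (uptake,
#' drains such as protein turnover) carry their own stoichiometry and a fixed
#' reference rate, closing the mass balance without being part of the
#' mechanistic parameterization. External (clamped) metabolites are declared
#' explicitly through `balanced` and are excluded from the mass balances but
#' may still appear in rate laws.
#'
#' @param metabolites character vector of metabolite identifiers (balanced
#'   and external).
#' @param S integer stoichiometric matrix, rows = `metabolites`, columns =
#'   `reactions`.
#' @param reactions character vector of reaction identifiers (unique).
#' @param balanced logical vector along `metabolites`; `TRUE` = mass balanced.
#' @param boundary named list of boundary fluxes, each
#'   `list(stoich = named numeric, v_ref = numeric)`.
#' @param pools list of moiety pools, each `list(members = character,
#'   total = numeric)`; the indicator over `members` must be a left null
#'   vector of the balanced submatrix of the full (reaction + boundary)
#'   stoichiometry.
#' @param mechanisms named list of [reaction_mechanism()] objects keyed by
#'   reaction id (may be filled later).
#' @return object of class `metabolic_network`.
#' @export
metabolic_network <- function(metabolites, S, reactions,
                              balanced = rep(TRUE, length(metabolites)),
                              boundary = list(), pools = list(),
                              mechanisms = list()) {
  S <- as.matrix(S)
  if (anyDuplicated(metabolites)) stop("duplicate metabolite identifiers")
  if (anyDuplicated(reactions)) stop("duplicate reaction identifiers")
  if (nrow(S) != length(metabolites) || ncol(S) != length(reactions)) {
    stop("S must be length(metabolites) x length(reactions)")
  }
  dimnames(S) <- list(metabolites, reactions)
  names(balanced) <- metabolites
  ## boundary stoichiometry as a full-height matrix
  Sb <- matrix(0, length(metabolites), length(boundary),
               dimnames = list(metabolites, names(boundary)))
  for (b in names(boundary)) {
    st <- boundary[[b]]$stoich
    if (!all(names(st) %in% metabolites)) {
      stop("boundary flux '", b, "' references unknown metabolites")
    }
    Sb[names(st), b] <- st
  }
  net <- structure(
    list(metabolites = metabolites, S = S, reactions = reactions,
         balanced = balanced, boundary = boundary, S_boundary = Sb,
         pools = pools, mechanisms = mechanisms),
    class = "metabolic_network")
  validate_network(net)
  net
}

#' @keywords internal
validate_network <- function(net) {
  bal <- net$balanced
  Sfull <- cbind(net$S, net$S_boundary)
  ## every balanced metabolite takes part in at least one reaction
  orphan <- rownames(Sfull)[bal & rowSums(Sfull != 0) == 0]
  if (length(orphan)) {
    stop("balanced metabolite(s) appear in no reaction: ",
         paste(orphan, collapse = ", "))
  }
  ## moiety pools: indicator is a left null vector of the balanced submatrix
  for (i in seq_along(net$pools)) {
    p <- net$pools[[i]]
    if (!all(p$members %in% net$metabolites)) {
      stop("moiety pool ", i, " references unknown metabolites")
    }
    ind <- as.numeric(net$metabolites %in% p$members)
    resid <- drop(ind %*% Sfull)
    if (any(resid != 0)) {
      stop("moiety pool {", paste(p$members, collapse = ", "),
           "} is not conserved: indicator'S is nonzero for reaction(s) ",
           paste(colnames(Sfull)[resid != 0], collapse = ", "))
    }
  }
  ## mechanisms, if attached, must match the column stoichiometry over the
  ## balanced metabolites (externals are free to appear only in the mechanism)
  for (rx in names(net$mechanisms)) {
    if (!rx %in% net$reactions) stop("mechanism for unknown reaction '", rx, "'")
    net_st <- route_net_stoich(net$mechanisms[[rx]], net$mechanisms[[rx]]$routes[[1L]])
    col <- net$S[, rx]
    for (m in net$metabolites[bal]) {
      want <- col[m]
      got <- if (m %in% names(net_st)) net_st[m] else 0
      if (want != got) {
        stop("mechanism '", rx, "' net stoichiometry disagrees with S for '",
             m, "'")
      }
    }
  }
  invisible(net)
}

#' Number of balanced metabolites / reactions
#' @param net a `metabolic_network`.
#' @export
n_balanced <- function(net) sum(net$balanced)

#' Balanced submatrix of the reaction (and optionally boundary) stoichiometry
#' @keywords internal
S_balanced <- function(net, with_boundary = FALSE) {
  S <- net$S[net$balanced, , drop = FALSE]
  if (with_boundary) S <- cbind(S, net$S_boundary[net$balanced, , drop = FALSE])
  S
}

#' Load a network from a structured model document
#'
#' Reads a YAML (or pre-parsed list) model specification with sections
#' `metabolites` (each with an `external` flag), `reactions` (stoichiometry,
#' mechanism name, binding/release order, allosteric effectors), `boundary`
#' and `pools`, and assembles a validated [metabolic_network()].
#'
#' @param spec path to a YAML file, or an already-parsed list.
#' @return a `metabolic_network`.
#' @export
load_network <- function(spec) {
  if (is.character(spec)) spec <- yaml::read_yaml(spec)
  mets <- vapply(spec$metabolites, function(m) m$id, character(1))
  balanced <- !vapply(spec$metabolites, function(m) isTRUE(m$external), logical(1))
  rxns <- vapply(spec$reactions, function(r) r$id, character(1))
  if (anyDuplicated(rxns)) stop("duplicate reaction identifiers in model spec")
  if (anyDuplicated(mets)) stop("duplicate metabolite identifiers in model spec")
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  mechanisms <- list()
  for (r in spec$reactions) {
    st <- unlist(r$stoichiometry)
    if (!all(names(st) %in% mets)) {
      stop("reaction '", r$id, "' references unknown metabolites")
    }
    S[names(st), r$id] <- st
    if (!is.null(r$mechanism)) {
      mechanisms[[r$id]] <- build_mechanism_from_spec(r)
    }
  }
  boundary <- list()
  for (b in spec$boundary %||% list()) {
    boundary[[b$id]] <- list(stoich = unlist(b$stoichiometry),
                             v_ref = as.numeric(b$v_ref %||% NA_real_))
  }
  pools <- lapply(spec$pools %||% list(), function(p) {
    list(members = as.character(unlist(p$members)),
         total = as.numeric(p$total %||% NA_real_))
  })
  metabolic_network(mets, S, rxns, balanced = balanced, boundary = boundary,
                    pools = pools, mechanisms = mechanisms)
}

#' @keywords internal
build_mechanism_from_spec <- function(r) {
  allo <- NULL
  if (!is.null(r$allosteric)) {
    allo <- list(n = r$allosteric$n %||% 1L,
                 activators = as.character(unlist(r$allosteric$activators %||% list())),
                 inhibitors = as.character(unlist(r$allosteric$inhibitors %||% list())))
  }
  kind <- r$mechanism$kind %||% "ordered"
  if (kind == "ordered") {
    mech_ordered(r$id,
                 bind = lapply(r$mechanism$bind, function(x) as.character(unlist(x))),
                 release = lapply(r$mechanism$release, function(x) as.character(unlist(x))),
                 allosteric = allo)
  } else if (kind == "random_bi") {
    mech_random_bi(r$id, subA = r$mechanism$subA, subB = r$mechanism$subB,
                   release = as.character(unlist(r$mechanism$release)),
                   allosteric = allo)
  } else {
    stop("unknown mechanism kind '", kind, "' for reaction '", r$id, "'")
  }
}

#' Reference operating point
#'
#' The anchoring state of the parameterization: a reference flux distribution
#' `v_ref` (mmol/L-cells/h) over the network's reactions, reference Gibbs
#' free energies `dG_r` (kJ/mol), enzyme levels `e_ref` (nominal 1) and
#' absolute reference metabolite concentrations `x_ref` for the balanced
#' metabolites (used for moiety weighting; rate laws operate on x/x_ref).
#'
#' @param v_ref named flux vector per reaction.
#' @param dG_r named Gibbs free energy per reaction at the reference (kJ/mol).
#' @param boundary_ref named boundary-flux reference values.
#' @param x_ref named absolute reference concentrations of balanced
#'   metabolites (defaults to 1).
#' @param e_ref named enzyme levels (defaults to 1).
#' @param RT gas constant times temperature, kJ/mol (default 2.5787, 37 C).
#' @export
reference_state <- function(v_ref, dG_r, boundary_ref = numeric(),
                            x_ref = NULL, e_ref = NULL, RT = 2.5787) {
  if (RT <= 0) stop("RT must be positive")
  if (is.null(e_ref)) e_ref <- stats::setNames(rep(1, length(v_ref)), names(v_ref))
  structure(list(v_ref = v_ref, dG_r = dG_r, boundary_ref = boundary_ref,
                 x_ref = x_ref, e_ref = e_ref, RT = RT),
            class = "reference_state")
}

#' Validate a reference state against a network
#'
#' Checks the steady-state balance S_balanced (v_ref, boundary_ref) = 0, the
#' thermodynamic sign condition sign(v_ref) = -sign(dG_r) for every
#' flux-carrying reaction, and reports missing Gibbs energies. Side-effect
#' free and idempotent.
#'
#' @param net a `metabolic_network`.
#' @param ref a `reference_state`.
#' @param tol relative balance tolerance (default 1e-9).
#' @return (invisibly) a list of diagnostics; raises an error on violations.
#' @export
validate_reference_state <- function(net, ref, tol = 1e-9) {
  v <- ref$v_ref[net$reactions]
  if (anyNA(v)) stop("v_ref missing for some reactions")
  vb <- ref$boundary_ref[names(net$boundary)]
  if (length(net$boundary) && anyNA(vb)) stop("boundary_ref missing entries")
  resid <- drop(S_balanced(net) %*% v)
  if (length(net$boundary)) {
    resid <- resid + drop(net$S_boundary[net$balanced, , drop = FALSE] %*% vb)
  }
  scale <- max(abs(v), abs(vb), 0)
  max_imbalance <- if (scale > 0) max(abs(resid)) / scale else max(abs(resid))
  warn <- character()
  if (scale == 0) warn <- c(warn, "all-zero reference flux")
  if (max_imbalance > tol) {
    stop(sprintf("reference flux imbalance %.3g exceeds tolerance %.3g (metabolite '%s')",
                 max_imbalance, tol,
                 rownames(S_balanced(net))[which.max(abs(resid))]))
  }
  dG <- ref$dG_r[net$reactions]
  missing_dG <- net$reactions[is.na(dG) & abs(v) > 0]
  if (length(missing_dG)) {
    stop("missing dG_r for flux-carrying reaction(s): ",
         paste(missing_dG, collapse = ", "))
  }
  conflict <- net$reactions[abs(v) > 0 & sign(v) != -sign(dG)]
  if (length(conflict)) {
    stop("flux/Gibbs-energy sign conflict for reaction(s): ",
         paste(conflict, collapse = ", "))
  }
  out <- list(max_imbalance = max_imbalance, sign_conflicts = conflict,
              missing_dG = missing_dG, warnings = warn)
  if (length(warn)) warning(paste(warn, collapse = "; "))
  invisible(out)
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat("<metabolic_network> ", sum(x$balanced), " balanced + ",
      sum(!x$balanced), " external metabolites, ", length(x$reactions),
      " reactions, ", length(x$boundary), " boundary fluxes, ",
      length(x$pools), " moiety pool(s)\n", sep = "")
  invisible(x)
}
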