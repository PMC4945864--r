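#' Thermodynamic input for Gibbs free energy range estimation
#'
#' @param dG0_r named standard Gibbs free energies of reaction (kJ/mol),
#'   already transformed to the condition of interest; contributions of
#'   clamped (external) metabolites are folded in.
#' @param ln_x_min,ln_x_max named log-concentration bounds (ln mol/L) for the
#'   balanced metabolites.
#' @param v_ref_signs named reaction direction signs (-1, 0, +1).
#' @param RT kJ/mol.
#' @export
thermo_input <- function(dG0_r, ln_x_min, ln_x_max, v_ref_signs, RT = 2.5787) {
  if (any(ln_x_min > ln_x_max)) stop("ln_x_min exceeds ln_x_max for some metabolite")
  miss <- names(v_ref_signs)[v_ref_signs != 0 & !(names(v_ref_signs) %in% names(dG0_r))]
  if (length(miss)) stop("dG0_r missing for flux-carrying reaction(s): ",
                         paste(miss, collapse = ", "))
  structure(list(dG0_r = dG0_r, ln_x_min = ln_x_min, ln_x_max = ln_x_max,
                 v_ref_signs = v_ref_signs, RT = RT),
            class = "thermo_input")
}

#' Read thermodynamic input tables
#'
#' Expects two delimited files: a reaction table with columns `reaction`,
#' `dG0` and a metabolite table with columns `metabolite`, `x_min`, `x_max`
#' (mol/L).
#' @param reaction_file,metabolite_file paths to TSV files.
#' @param v_ref_signs named direction signs.
#' @param RT kJ/mol.
#' @export
read_thermo_tables <- function(reaction_file, metabolite_file, v_ref_signs,
                               RT = 2.5787) {
  rt <- utils::read.delim(reaction_file, stringsAsFactors = FALSE)
  mt <- utils::read.delim(metabolite_file, stringsAsFactors = FALSE)
  thermo_input(dG0_r = stats::setNames(rt$dG0, rt$reaction),
               ln_x_min = stats::setNames(log(mt$x_min), mt$metabolite),
               ln_x_max = stats::setNames(log(mt$x_max), mt$metabolite),
               v_ref_signs = v_ref_signs, RT = RT)
}

#' Feasible Gibbs free energy ranges (thermodynamic variability analysis)
#'
#' For each reaction j, minimizes and maximizes
#' \deqn{\Delta G_{r,j} = \Delta G^0_j + RT\, S_j^\top \ln x}
#' over box bounds on ln x, subject to the direction constraint
#' \eqn{sign(v_k)\,\Delta G_{r,k} \le -\epsilon} for every flux-carrying
#' reaction k. When *maximizing* reaction j, its own direction constraint is
#' relaxed: the maximum answers whether the reaction could thermodynamically
#' reverse while the rest of the network keeps its reference directions, which
#' is what the reversibility classification asks. A reaction is labelled
#' `strictly_irreversible` when even that relaxed maximum stays negative (for
#' forward reactions; symmetrically for reverse), `near_equilibrium` when its
#' midpoint driving force is within 2 RT of zero, and `reversible` otherwise.
#'
#' @param net a `metabolic_network` (balanced metabolites define the ln x
#'   variables).
#' @param thermo a [thermo_input()].
#' @param eps_dir strictness of the direction inequality (kJ/mol).
#' @return data.frame with columns `reaction`, `dG_min`, `dG_max`,
#'   `midpoint`, `reversibility_label`, `lp_status`; class `gibbs_ranges`.
#' @export
gibbs_ranges <- function(net, thermo, eps_dir = 1e-6) {
  mets <- net$metabolites[net$balanced]
  rxns <- net$reactions
  lo <- thermo$ln_x_min[mets]; hi <- thermo$ln_x_max[mets]
  if (anyNA(lo) || anyNA(hi)) stop("concentration bounds missing for some balanced metabolite")
  RT <- thermo$RT
  Sb <- S_balanced(net)
  sgn <- thermo$v_ref_signs[rxns]
  dG0 <- thermo$dG0_r[rxns]
  nv <- length(mets)
  width <- hi - lo
  carrying <- which(sgn != 0)

  ## direction constraints in shifted variables y = ln x - lo (y >= 0):
  ## sign_k * RT * S_k' y <= -eps - sign_k * (dG0_k + RT * S_k' lo)
  dir_A <- t(Sb[, carrying, drop = FALSE]) * (RT * sgn[carrying])
  dir_b <- -eps_dir - sgn[carrying] * (dG0[carrying] + drop(crossprod(Sb[, carrying, drop = FALSE], lo)))
  ub_A <- diag(nv); ub_b <- width

  solve_lp <- function(obj, keep, maximize) {
    A1 <- rbind(ub_A, dir_A[keep, , drop = FALSE])
    b1 <- c(ub_b, dir_b[keep])
    res <- boot::simplex(a = obj, A1 = A1, b1 = b1, maxi = maximize)
    if (res$solved != 1) return(list(ok = FALSE, val = NA_real_))
    list(ok = TRUE, val = sum(obj * res$soln))
  }

  out <- data.frame(reaction = rxns, dG_min = NA_real_, dG_max = NA_real_,
                    midpoint = NA_real_, reversibility_label = NA_character_,
                    lp_status = "ok", stringsAsFactors = FALSE)
  for (j in seq_along(rxns)) {
    obj <- RT * Sb[, j]
    const <- dG0[j] + sum(RT * Sb[, j] * lo)
    keep_all <- seq_along(carrying)
    keep_rel <- keep_all[carrying != j]
    lo_lp <- solve_lp(obj, keep_all, maximize = FALSE)
    hi_lp <- solve_lp(obj, keep_rel, maximize = TRUE)
    if (!lo_lp$ok || !hi_lp$ok) {
      out$lp_status[j] <- "infeasible"
      next
    }
    out$dG_min[j] <- const + lo_lp$val
    out$dG_max[j] <- const + hi_lp$val
  }
  if (any(out$lp_status != "ok")) {
    stop("thermodynamically inconsistent reference data: direction ",
         "constraints infeasible when ranging reaction(s) ",
         paste(out$reaction[out$lp_status != "ok"], collapse = ", "))
  }
  out$midpoint <- (out$dG_min + out$dG_max) / 2
  irr <- ifelse(sgn >= 0, out$dG_max < 0, out$dG_min > 0)
  neareq <- abs(out$midpoint) < 2 * RT
  out$reversibility_label <- ifelse(irr, "strictly_irreversible",
                                    ifelse(neareq, "near_equilibrium", "reversible"))
  class(out) <- c("gibbs_ranges", class(out))
  out
}

#' Representative reference Gibbs free energies
#'
#' Returns the midpoint of each feasible range as the representative
#' thermodynamic reference, or uniform draws within the ranges when
#' `sample = TRUE`.
#'
#' @param ranges result of [gibbs_ranges()].
#' @param sample draw uniformly within each range instead of the midpoint.
#' @param seed optional RNG seed for the sampling hook.
#' @return named numeric vector of dG_r (kJ/mol).
#' @export
reference_dG <- function(ranges, sample = FALSE, seed = NULL) {
  if (sample) {
    if (!is.null(seed)) set.seed(seed)
    val <- stats::runif(nrow(ranges), ranges$dG_min, ranges$dG_max)
  } else {
    val <- ranges$midpoint
  }
  stats::setNames(val, ranges$reaction)
}
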