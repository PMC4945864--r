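#' Flux control coefficients by central finite differences
#'
#' C_ij = (E_j / v_i) (dv_i / dE_j) computed with a central difference of
#' 0.01% (step 1e-4) on each activity. Columns cover every scalable activity
#' of the model: the enzymes of all reactions plus the boundary fluxes (with
#' constant boundary fluxes the summation theorem Sum_j C_ij = 1 only closes
#' over this full activity set). Rows with |v_i| below `flux_floor` are
#' flagged undefined (NA). Solver failure at a perturbed point flags the
#' whole column missing.
#'
#' @param model a [kinetic_model()].
#' @param base_pert optional base [perturbation()] defining the condition.
#' @param step relative finite-difference step (default 1e-4 = 0.01%).
#' @param flux_floor fluxes below this are treated as undefined rows.
#' @return object of class `control_matrix`: list with `C` (rows = reaction
#'   fluxes, cols = activities), `summation_deviation`, `state_label`.
#' @export
flux_control_coefficients <- function(model, base_pert = NULL, step = 1e-4,
                                      flux_floor = 1e-9) {
  net <- model$net
  base <- solve_steady_state(model, base_pert)
  if (!base$converged) stop("base steady state did not converge")
  rxns <- net$reactions
  acts <- c(rxns, names(net$boundary))
  C <- matrix(NA_real_, length(rxns), length(acts),
              dimnames = list(rxns, acts))
  v0 <- base$v[rxns]
  defined <- abs(v0) >= flux_floor
  e0 <- stats::setNames(rep(1, length(rxns)), rxns)
  b0 <- stats::setNames(rep(1, length(net$boundary)), names(net$boundary))
  if (!is.null(base_pert)) {
    e0[names(base_pert$enzymes)] <- base_pert$enzymes
    b0[names(base_pert$boundary)] <- base_pert$boundary
  }
  perturb_at <- function(act, fac) {
    e <- e0; b <- b0
    if (act %in% rxns) e[act] <- e[act] * fac else b[act] <- b[act] * fac
    perturbation(paste0("fcc_", act), enzymes = e, boundary = b)
  }
  for (a in acts) {
    up <- solve_steady_state(model, perturb_at(a, 1 + step), x0 = base$x,
                             fallback = FALSE)
    dn <- solve_steady_state(model, perturb_at(a, 1 - step), x0 = base$x,
                             fallback = FALSE)
    if (!up$converged || !dn$converged) next
    C[defined, a] <- (up$v[rxns][defined] - dn$v[rxns][defined]) /
      (2 * step * v0[defined])
  }
  sumdev <- abs(rowSums(C) - 1)
  structure(list(C = C, summation_deviation = sumdev,
                 state_label = if (is.null(base_pert)) "reference" else base_pert$label),
            class = "control_matrix")
}

#' Ensemble-expected control structure
#'
#' Applies [posterior_expectancy()] with the flux-control-coefficient
#' functional over a particle set; particles whose FCC computation fails are
#' excluded and counted.
#'
#' @param pset a `particle_set`.
#' @param base_pert condition at which the control structure is evaluated.
#' @param step finite-difference step.
#' @param level credible level for the per-entry intervals.
#' @param max_summation_dev validity filter: particles whose worst row
#'   deviates from the summation theorem by more than this are excluded
#'   (and counted in `n_skipped`); `NULL` disables the filter.
#' @return list with `mean` (control matrix), `lower`, `upper`, `n_used`,
#'   `n_skipped`, `summation_deviation` (worst row deviation across used
#'   particles).
#' @export
control_structure_summary <- function(pset, base_pert = NULL, step = 1e-4,
                                      level = 0.95,
                                      max_summation_dev = 0.01) {
  plan <- rate_plan(pset$net, pset$ref)
  dims <- NULL
  worst_dev <- 0
  fcc_fun <- function(p) {
    model <- ensemble_model(pset$net, pset$ref, p, plan = plan)
    cm <- flux_control_coefficients(model, base_pert = base_pert, step = step)
    if (anyNA(cm$C)) stop("undefined control entries")
    dev <- max(cm$summation_deviation)
    if (!is.null(max_summation_dev) && dev > max_summation_dev) {
      stop("summation-theorem validity filter")
    }
    worst_dev <<- max(worst_dev, dev)
    dims <<- dimnames(cm$C)
    as.vector(cm$C)
  }
  ex <- posterior_expectancy(pset, fcc_fun, level = level)
  shape <- function(v) matrix(v, length(dims[[1]]), length(dims[[2]]),
                              dimnames = dims)
  list(mean = shape(ex$mean), lower = shape(ex$lower), upper = shape(ex$upper),
       n_used = ex$n_used, n_skipped = ex$n_skipped,
       summation_deviation = worst_dev)
}

#' Entrywise RMSE between two control matrices
#'
#' Pairwise-defined entries only (NA in either matrix is excluded).
#' @param A,B control coefficient matrices of matching shape.
#' @export
fcc_rmse <- function(A, B) {
  if (inherits(A, "control_matrix")) A <- A$C
  if (inherits(B, "control_matrix")) B <- B$C
  if (!identical(dim(A), dim(B))) stop("control matrices differ in shape")
  d <- (A - B)^2
  sqrt(mean(d[!is.na(d)]))
}

#' Sign agreement of control structures (Matthews correlation)
#'
#' Binarizes entries by sign; entries with |C| below the dead zone in either
#' matrix are excluded as a zero class. Returns the Matthews correlation
#' coefficient over the +/- classes and the confusion counts.
#'
#' @param predicted,truth control matrices (or `control_matrix` objects).
#' @param dead_zone magnitude below which an entry is treated as zero.
#' @export
control_sign_agreement <- function(predicted, truth, dead_zone = 1e-3) {
  if (inherits(predicted, "control_matrix")) predicted <- predicted$C
  if (inherits(truth, "control_matrix")) truth <- truth$C
  if (!identical(dim(predicted), dim(truth))) stop("shape mismatch")
  keep <- !is.na(predicted) & !is.na(truth) &
    abs(predicted) >= dead_zone & abs(truth) >= dead_zone
  if (!any(keep)) stop("all entries excluded by the dead zone")
  p <- predicted[keep] > 0
  t <- truth[keep] > 0
  tp <- sum(p & t); tn <- sum(!p & !t); fp <- sum(p & !t); fn <- sum(!p & t)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
  list(mcc = mcc, TP = tp, TN = tn, FP = fp, FN = fn, n_used = sum(keep),
       n_excluded = sum(!keep))
}
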