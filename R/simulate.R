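#' Perturbation of enzyme levels and boundary fluxes
#'
#' @param label identifier.
#' @param enzymes named positive multipliers on enzyme levels (unmentioned
#'   reactions default to 1).
#' @param boundary named positive multipliers on boundary fluxes.
#' @param boundary_add named additive changes on boundary fluxes
#'   (applied after the multiplier).
#' @export
perturbation <- function(label = "pert", enzymes = numeric(),
                         boundary = numeric(), boundary_add = numeric()) {
  if (length(enzymes) && any(enzymes <= 0)) stop("enzyme multipliers must be positive")
  if (length(boundary) && any(boundary <= 0)) stop("boundary multipliers must be positive")
  structure(list(label = label, enzymes = enzymes, boundary = boundary,
                 boundary_add = boundary_add),
            class = "perturbation")
}

#' Executable kinetic model on a network
#'
#' Couples a network's stoichiometry with a flux evaluator. `flux_fun` maps
#' the balanced-metabolite concentration vector (in the model's concentration
#' units) plus enzyme/boundary multipliers to reaction and boundary fluxes.
#' `conc_scale` converts flux imbalances to concentration time derivatives,
#' dx/dt = (S v + S_b v_b) / conc_scale, so ensemble models can operate on
#' normalized concentrations while fixture models use absolute ones.
#'
#' @param net `metabolic_network`; @param ref `reference_state`.
#' @param flux_fun function(x_bal, e_mult, b_mult, b_add) -> list(v, vb).
#' @param conc_scale named vector over balanced metabolites.
#' @param x0 default initial concentrations (balanced metabolites).
#' @param label model label.
#' @export
kinetic_model <- function(net, ref, flux_fun, conc_scale, x0, label = "model") {
  bal <- net$metabolites[net$balanced]
  structure(list(net = net, ref = ref, flux_fun = flux_fun,
                 conc_scale = conc_scale[bal], x0 = x0[bal], label = label),
            class = "kinetic_model")
}

#' Ensemble model: one sampled particle on the network
#'
#' Operates on normalized concentrations (reference = 1); external
#' metabolites are clamped at 1.
#' @param net network; @param ref reference state; @param particle particle.
#' @param plan optional precompiled [rate_plan()].
#' @export
ensemble_model <- function(net, ref, particle, plan = NULL) {
  if (is.null(plan)) plan <- rate_plan(net, ref)
  mets <- net$metabolites
  bal <- mets[net$balanced]
  bal_idx <- which(net$balanced)
  x_full0 <- stats::setNames(rep(1, length(mets)), mets)
  bnames <- names(net$boundary)
  vb_ref <- ref$boundary_ref[bnames]
  flux_fun <- function(x_bal, e_mult, b_mult, b_add) {
    x_full <- x_full0
    x_full[bal_idx] <- x_bal
    v <- network_fluxes(plan, particle, x_full, e_mult)
    vb <- vb_ref * b_mult + b_add
    list(v = v, vb = vb)
  }
  xr <- ref$x_ref
  if (is.null(xr)) xr <- stats::setNames(rep(1, length(bal)), bal)
  model <- kinetic_model(net, ref, flux_fun, conc_scale = xr,
                         x0 = stats::setNames(rep(1, length(bal)), bal),
                         label = "ensemble_particle")
  ## compiled fast path: packed plan + particle for the C++ Newton solver
  model$cpp <- list(plan = plan$packed,
                    particle = pack_particle(plan, particle),
                    x_template = x_full0, bal_idx = bal_idx,
                    vb_ref = vb_ref)
  model
}

#' @keywords internal
sim_plan <- function(model) {
  net <- model$net
  bal <- net$metabolites[net$balanced]
  Sb <- S_balanced(net)
  Sbb <- net$S_boundary[net$balanced, , drop = FALSE]
  elim <- integer(0); pools <- list()
  for (p in net$pools) {
    mem <- match(p$members, bal)
    if (anyNA(mem)) stop("moiety pool member is not a balanced metabolite")
    w <- model$conc_scale[mem]
    pools[[length(pools) + 1L]] <-
      list(members = mem, w = w, elim = mem[length(mem)],
           keep = mem[-length(mem)],
           total = sum(w * model$x0[mem]))
    elim <- c(elim, mem[length(mem)])
  }
  dyn <- setdiff(seq_along(bal), elim)
  list(bal = bal, S = Sb, Sb = Sbb, pools = pools, dyn = dyn, elim = elim)
}

#' @keywords internal
expand_state <- function(sp, x_dyn, x_template) {
  x <- x_template
  x[sp$dyn] <- x_dyn
  for (p in sp$pools) {
    x[p$elim] <- (p$total - sum(p$w[-length(p$w)] * x[p$keep])) / p$w[length(p$w)]
  }
  x
}

#' Solve a perturbed steady state
#'
#' Finds metabolite concentrations with S v = 0 over the balanced metabolites
#' and moiety totals conserved. Strategy: damped Newton on the reduced system
#' (moieties eliminated) from `x0`; on failure, stiff ODE integration
#' (deSolve::lsoda) toward the attractor followed by a Newton polish.
#' Non-convergence is a first-class outcome (`converged = FALSE`), not an
#' error, so ABC loops can count such particles as rejections.
#'
#' @param model a [kinetic_model()].
#' @param pert a [perturbation()] (NULL = reference condition).
#' @param x0 initial concentrations over balanced metabolites (default:
#'   the model's reference).
#' @param tol relative flux-imbalance tolerance (default 1e-9 of max |v_ref|).
#' @param max_newton Newton iteration budget.
#' @param integrate_horizon total ODE integration budget (model hours).
#' @param x_divergence concentration magnitude beyond which the trajectory is
#'   declared divergent (no steady state in a physical range).
#' @param fallback try the stiff-integration fallback when Newton fails
#'   (disabled inside rejection loops, where a failed solve is simply a
#'   rejected particle).
#' @return object of class `steady_state` with fields `x`, `v`, `v_boundary`,
#'   `converged`, `residual`, `solver_report`.
#' @export
solve_steady_state <- function(model, pert = NULL, x0 = NULL, tol = 1e-9,
                               max_newton = 40L, integrate_horizon = 1e6,
                               x_divergence = 1e5, fallback = TRUE) {
  net <- model$net
  sp <- sim_plan(model)
  e_mult <- stats::setNames(rep(1, length(net$reactions)), net$reactions)
  b_mult <- stats::setNames(rep(1, length(net$boundary)), names(net$boundary))
  b_add <- stats::setNames(rep(0, length(net$boundary)), names(net$boundary))
  if (!is.null(pert)) {
    e_mult[names(pert$enzymes)] <- pert$enzymes
    b_mult[names(pert$boundary)] <- pert$boundary
    if (length(pert$boundary_add)) b_add[names(pert$boundary_add)] <- pert$boundary_add
  }
  x_template <- model$x0
  vscale <- max(abs(model$ref$v_ref), abs(model$ref$boundary_ref), 1e-12)
  atol <- tol * vscale

  imbalance <- function(x_bal) {
    fl <- model$flux_fun(x_bal, e_mult, b_mult, b_add)
    drop(sp$S %*% fl$v) + (if (ncol(sp$Sb)) drop(sp$Sb %*% fl$vb) else 0)
  }
  gfun <- function(x_dyn) {
    x <- expand_state(sp, x_dyn, x_template)
    if (any(x <= 0)) return(rep(NA_real_, length(sp$dyn)))
    imbalance(x)[sp$dyn]
  }

  start <- if (is.null(x0)) model$x0 else x0[sp$bal]
  if (!is.null(model$cpp)) {
    vb <- model$cpp$vb_ref * b_mult + b_add
    cvec <- if (ncol(sp$Sb)) {
      drop(sp$Sb[sp$dyn, , drop = FALSE] %*% vb)
    } else rep(0, length(sp$dyn))
    cpools <- lapply(sp$pools, function(p) {
      list(elim = p$elim, keep = p$keep, w = unname(p$w), total = p$total)
    })
    res <- cpp_solve_steady(model$cpp$plan, model$cpp$particle,
                            unname(model$cpp$x_template),
                            model$cpp$bal_idx,
                            sp$S[sp$dyn, , drop = FALSE], cvec,
                            sp$dyn, cpools,
                            unname(e_mult[model$net$reactions]),
                            unname(start[sp$dyn]),
                            atol, max_newton, 1e5)
    method <- "newton(c)"
  } else {
    res <- newton_steady(gfun, start[sp$dyn], atol, max_newton)
    method <- "newton"
  }
  if (!res$converged && !isTRUE(res$diverged) && fallback) {
    cpp_imbalance <- NULL
    if (!is.null(model$cpp)) {
      rx_idx <- seq_along(model$net$reactions)
      cpp_imbalance <- function(x_bal) {
        xf <- model$cpp$x_template
        xf[model$cpp$bal_idx] <- x_bal
        v <- cpp_network_fluxes(model$cpp$plan, model$cpp$particle,
                                unname(xf), unname(e_mult[rx_idx]))
        vb <- model$cpp$vb_ref * b_mult + b_add
        drop(sp$S %*% v) + (if (ncol(sp$Sb)) drop(sp$Sb %*% vb) else 0)
      }
    }
    ode_fun <- function(t, y, parms) {
      x <- expand_state(sp, y, x_template)
      x[x <= 0] <- 1e-12
      imb <- if (is.null(cpp_imbalance)) imbalance(x) else cpp_imbalance(x)
      list(imb[sp$dyn] / model$conc_scale[sp$dyn])
    }
    y <- pmax(start[sp$dyn], 1e-9)
    horizons <- c(1e2, 1e4, integrate_horizon)
    for (h in horizons) {
      sol <- tryCatch(
        deSolve::lsoda(y, times = c(0, h), func = ode_fun, parms = NULL,
                       rtol = 1e-8, atol = 1e-12, maxsteps = 2000),
        error = function(e) NULL, warning = function(w) NULL)
      if (is.null(sol) || nrow(sol) < 2L || anyNA(sol[2L, -1L])) break
      y <- pmax(as.numeric(sol[2L, -1L]), 1e-12)
      ## no steady state in a physical range: stop chasing a divergence
      if (max(y) > x_divergence) break
      res2 <- newton_steady(gfun, y, atol, max_newton)
      if (res2$converged) { res <- res2; method <- "integrate+newton"; break }
    }
  }
  x_bal <- expand_state(sp, res$x, x_template)
  names(x_bal) <- sp$bal
  fl <- model$flux_fun(x_bal, e_mult, b_mult, b_add)
  structure(list(x = x_bal, v = fl$v, v_boundary = fl$vb,
                 converged = res$converged && all(x_bal > 0),
                 residual = res$resid,
                 solver_report = list(method = method, iterations = res$iter),
                 perturbation = if (is.null(pert)) "reference" else pert$label),
            class = "steady_state")
}

#' Damped Newton iteration on the reduced steady-state system
#' @keywords internal
newton_steady <- function(gfun, x, atol, max_iter = 100L) {
  g <- gfun(x)
  if (anyNA(g)) return(list(x = x, converged = FALSE, resid = Inf, iter = 0L))
  nrm <- max(abs(g))
  iter <- 0L
  J <- NULL
  stale <- TRUE
  fails <- 0L
  while (nrm > atol && iter < max_iter) {
    iter <- iter + 1L
    if (stale) {
      J <- num_jacobian(gfun, x, g)
      stale <- FALSE
    }
    dx <- tryCatch(solve(J, -g), error = function(e) NULL)
    if (is.null(dx) || anyNA(dx)) {
      if (!stale) break
      stale <- TRUE; next
    }
    lambda <- 1
    ok <- FALSE
    while (lambda >= 1e-4) {
      xn <- x + lambda * dx
      ## keep concentrations away from zero
      if (all(xn > 0)) {
        gn <- gfun(xn)
        if (!anyNA(gn) && max(abs(gn)) < nrm * (1 - 0.25 * lambda) + atol) {
          x <- xn
          ## chord variant: reuse the Jacobian while progress is fast
          stale <- lambda < 1 || max(abs(gn)) > 0.2 * nrm
          g <- gn; nrm <- max(abs(gn)); ok <- TRUE; fails <- 0L
          break
        }
      }
      lambda <- lambda / 2
    }
    if (!ok) {
      fails <- fails + 1L
      if (fails >= 2L) break    # a fresh Jacobian made no progress either
      stale <- TRUE             # retry once with a fresh Jacobian
    }
  }
  list(x = x, converged = nrm <= atol, resid = nrm, iter = iter)
}

#' Forward-difference Jacobian
#' @keywords internal
num_jacobian <- function(gfun, x, g0 = NULL) {
  n <- length(x)
  if (is.null(g0)) g0 <- gfun(x)
  J <- matrix(0, length(g0), n)
  for (j in seq_len(n)) {
    h <- 1e-7 * max(abs(x[j]), 1e-3)
    xp <- x; xp[j] <- xp[j] + h
    gp <- gfun(xp)
    if (anyNA(gp)) { xp[j] <- x[j] - h; gp <- gfun(xp); h <- -h }
    J[, j] <- (gp - g0) / h
  }
  J
}

#' Local stability of a steady state
#'
#' Builds the Jacobian of the reduced ODE system (one metabolite per moiety
#' pool eliminated) by central finite differences and reports stability
#' (all eigenvalue real parts negative) plus the leading real part (1/h).
#'
#' @param model a `kinetic_model`; @param state a converged `steady_state`.
#' @param pert the perturbation under which the state was computed.
#' @param rel_step relative finite-difference step.
#' @export
jacobian_stability <- function(model, state, pert = NULL, rel_step = 1e-6) {
  if (!isTRUE(state$converged)) stop("state has not converged")
  net <- model$net
  sp <- sim_plan(model)
  e_mult <- stats::setNames(rep(1, length(net$reactions)), net$reactions)
  b_mult <- stats::setNames(rep(1, length(net$boundary)), names(net$boundary))
  b_add <- stats::setNames(rep(0, length(net$boundary)), names(net$boundary))
  if (!is.null(pert)) {
    e_mult[names(pert$enzymes)] <- pert$enzymes
    b_mult[names(pert$boundary)] <- pert$boundary
    if (length(pert$boundary_add)) b_add[names(pert$boundary_add)] <- pert$boundary_add
  }
  fdot <- function(x_dyn) {
    x <- expand_state(sp, x_dyn, state$x)
    fl <- model$flux_fun(x, e_mult, b_mult, b_add)
    resid <- drop(sp$S %*% fl$v) + (if (ncol(sp$Sb)) drop(sp$Sb %*% fl$vb) else 0)
    (resid / model$conc_scale)[sp$dyn]
  }
  x <- state$x[sp$dyn]
  n <- length(x)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- rel_step * max(abs(x[j]), 1e-6)
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    J[, j] <- (fdot(xp) - fdot(xm)) / (2 * h)
  }
  ev <- eigen(J, only.values = TRUE)$values
  lead <- max(Re(ev))
  list(stable = lead < 0, leading_real_part = lead, eigenvalues = ev)
}
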