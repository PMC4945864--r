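#' Compile a network into a rate-evaluation plan
#'
#' Precomputes integer index structures (state indices, bound/released
#' metabolite indices, catalytic steps, allosteric effector indices) for fast
#' repeated evaluation of the QSSA rate laws. Reactions with negative
#' reference flux are re-oriented so that sampling and assembly always
#' proceed along the net flux direction.
#'
#' @param net a `metabolic_network` with mechanisms for every reaction.
#' @param ref a [reference_state()].
#' @return an opaque plan object used by the evaluation routines.
#' @export
rate_plan <- function(net, ref) {
  mets <- net$metabolites
  plan_rx <- vector("list", length(net$reactions))
  names(plan_rx) <- net$reactions
  oriented <- list()
  orientation <- list()
  for (rx in net$reactions) {
    mech <- net$mechanisms[[rx]]
    if (is.null(mech)) stop("no mechanism attached for reaction '", rx, "'")
    o <- if (ref$v_ref[[rx]] < 0) -1 else 1
    if (o < 0) mech <- flip_mechanism(mech)
    oriented[[rx]] <- mech
    orientation[[rx]] <- o
    ns <- length(mech$states)
    m <- length(mech$steps)
    from <- match(vapply(mech$steps, `[[`, character(1), "from"), mech$states)
    to <- match(vapply(mech$steps, `[[`, character(1), "to"), mech$states)
    bind <- lapply(mech$steps, function(s) match(s$bind, mets))
    rel <- lapply(mech$steps, function(s) match(s$release, mets))
    if (anyNA(unlist(c(bind, rel)))) {
      stop("mechanism '", rx, "' references metabolites absent from the network")
    }
    cat_steps <- which(vapply(mech$steps, `[[`, logical(1), "catalytic"))
    al <- mech$allosteric
    allo <- NULL
    if (!is.null(al)) {
      allo <- list(n = al$n,
                   act_idx = match(al$activators, mets),
                   inh_idx = match(al$inhibitors, mets))
      if (anyNA(c(allo$act_idx, allo$inh_idx))) {
        stop("allosteric effector of '", rx, "' absent from the network")
      }
    }
    ## single catalytic cycle in route order: closed-form King-Altman path
    cycle <- ns == m && identical(from, seq_len(m)) &&
      identical(to, c(seq_len(m)[-1L], 1L))
    plan_rx[[rx]] <- list(ns = ns, m = m, from = from, to = to,
                          bind = bind, rel = rel, cat = cat_steps,
                          allosteric = allo, orientation = o,
                          cycle = cycle && m %in% c(2L, 3L, 4L))
  }
  list(reactions = plan_rx, oriented = oriented,
       orientation = orientation, metabolites = mets,
       n_reactions = length(net$reactions),
       packed = pack_plan(plan_rx, length(mets)))
}

#' Flat integer representation of a rate plan for the compiled backend
#' @keywords internal
pack_plan <- function(plan_rx, nmet) {
  nrx <- length(plan_rx)
  ns <- vapply(plan_rx, `[[`, integer(1), "ns")
  m <- vapply(plan_rx, function(p) as.integer(p$m), integer(1))
  cyc <- vapply(plan_rx, function(p) as.integer(isTRUE(p$cycle)), integer(1))
  ori <- vapply(plan_rx, function(p) as.integer(p$orientation), integer(1))
  step_off <- c(0L, cumsum(m))
  from <- unlist(lapply(plan_rx, `[[`, "from"), use.names = FALSE)
  to <- unlist(lapply(plan_rx, `[[`, "to"), use.names = FALSE)
  is_cat <- unlist(lapply(plan_rx, function(p) {
    z <- integer(p$m); z[p$cat] <- 1L; z
  }), use.names = FALSE)
  binds <- unlist(lapply(plan_rx, `[[`, "bind"), recursive = FALSE,
                  use.names = FALSE)
  rels <- unlist(lapply(plan_rx, `[[`, "rel"), recursive = FALSE,
                 use.names = FALSE)
  bind_off <- c(0L, cumsum(vapply(binds, length, integer(1))))
  rel_off <- c(0L, cumsum(vapply(rels, length, integer(1))))
  allo_n <- vapply(plan_rx, function(p) {
    if (is.null(p$allosteric)) 0L else as.integer(p$allosteric$n)
  }, integer(1))
  acts <- lapply(plan_rx, function(p) {
    if (is.null(p$allosteric)) integer() else as.integer(p$allosteric$act_idx)
  })
  inhs <- lapply(plan_rx, function(p) {
    if (is.null(p$allosteric)) integer() else as.integer(p$allosteric$inh_idx)
  })
  list(nrx = nrx, nmet = as.integer(nmet), nsteps = sum(m),
       ns = as.integer(ns), m = m, cyc = cyc, ori = ori,
       step_off = step_off, from = as.integer(from), to = as.integer(to),
       is_cat = as.integer(is_cat),
       bind_off = bind_off,
       bind_idx = as.integer(unlist(binds, use.names = FALSE)),
       rel_off = rel_off,
       rel_idx = as.integer(unlist(rels, use.names = FALSE)),
       allo_n = allo_n,
       act_off = c(0L, cumsum(vapply(acts, length, integer(1)))),
       act_idx = as.integer(unlist(acts, use.names = FALSE)),
       inh_off = c(0L, cumsum(vapply(inhs, length, integer(1)))),
       inh_idx = as.integer(unlist(inhs, use.names = FALSE)))
}

#' Flat numeric representation of a particle for the compiled backend
#' @keywords internal
pack_particle <- function(plan, particle) {
  rxs <- particle$reactions
  kf <- unlist(lapply(rxs, `[[`, "kf"), use.names = FALSE)
  kr <- unlist(lapply(rxs, `[[`, "kr"), use.names = FALSE)
  nrx <- length(rxs)
  L <- rep(NA_real_, nrx); Qref <- rep(NA_real_, nrx)
  K <- numeric(0)
  K_act_off <- integer(nrx); K_inh_off <- integer(nrx)
  pos <- 0L
  for (j in seq_len(nrx)) {
    al <- rxs[[j]]$allosteric
    K_act_off[j] <- pos
    if (!is.null(al)) {
      L[j] <- al$L; Qref[j] <- al$Q_ref
      K <- c(K, unname(al$K_act))
      pos <- pos + length(al$K_act)
      K_inh_off[j] <- pos
      K <- c(K, unname(al$K_inh))
      pos <- pos + length(al$K_inh)
    } else {
      K_inh_off[j] <- pos
    }
  }
  list(kf = as.numeric(kf), kr = as.numeric(kr), L = L, Qref = Qref,
       K = as.numeric(K), K_act_off = K_act_off, K_inh_off = K_inh_off)
}

#' Evaluate one reaction's QSSA rate law
#'
#' Solves the enzyme-state linear system (elementary-step balances with
#' total-enzyme normalization) at the given metabolite concentrations and
#' returns the net catalytic flux through the catalytic step(s), multiplied
#' by the enzyme level and the MWC regulatory factor.
#'
#' @param prx compiled per-reaction plan entry.
#' @param pp per-reaction particle entry (kf, kr, allosteric).
#' @param x full metabolite vector in normalized concentration units
#'   (externals clamped at 1).
#' @param e enzyme level relative to reference.
#' @keywords internal
eval_reaction_flux <- function(prx, pp, x, e = 1) {
  m <- prx$m
  wf <- pp$kf
  wr <- pp$kr
  for (i in seq_len(m)) {
    bi <- prx$bind[[i]]
    if (length(bi)) wf[i] <- wf[i] * prod(x[bi])
    ri <- prx$rel[[i]]
    if (length(ri)) wr[i] <- wr[i] * prod(x[ri])
  }
  if (prx$cycle) {
    ## closed-form net cycle flux: (prod f - prod b) / sum of rooted trees
    if (m == 2L) {
      f1 <- wf[1L]; f2 <- wf[2L]; b1 <- wr[1L]; b2 <- wr[2L]
      den <- f1 + f2 + b1 + b2
      v <- (f1 * f2 - b1 * b2) / den
    } else if (m == 3L) {
      f1 <- wf[1L]; f2 <- wf[2L]; f3 <- wf[3L]
      b1 <- wr[1L]; b2 <- wr[2L]; b3 <- wr[3L]
      den <- f2 * f3 + f3 * b1 + b1 * b2 +
        f3 * f1 + f1 * b2 + b2 * b3 +
        f1 * f2 + f2 * b3 + b3 * b1
      v <- (f1 * f2 * f3 - b1 * b2 * b3) / den
    } else {
      f1 <- wf[1L]; f2 <- wf[2L]; f3 <- wf[3L]; f4 <- wf[4L]
      b1 <- wr[1L]; b2 <- wr[2L]; b3 <- wr[3L]; b4 <- wr[4L]
      den <- f2 * f3 * f4 + b1 * f3 * f4 + b1 * b2 * f4 + b1 * b2 * b3 +
        f3 * f4 * f1 + b2 * f4 * f1 + b2 * b3 * f1 + b2 * b3 * b4 +
        f4 * f1 * f2 + b3 * f1 * f2 + b3 * b4 * f2 + b3 * b4 * b1 +
        f1 * f2 * f3 + b4 * f2 * f3 + b4 * b1 * f3 + b4 * b1 * b2
      v <- (f1 * f2 * f3 * f4 - b1 * b2 * b3 * b4) / den
    }
  } else {
    ns <- prx$ns
    A <- matrix(0, ns, ns)
    fr <- prx$from; to <- prx$to
    for (i in seq_len(m)) {
      A[to[i], fr[i]] <- A[to[i], fr[i]] + wf[i]
      A[fr[i], fr[i]] <- A[fr[i], fr[i]] - wf[i]
      A[fr[i], to[i]] <- A[fr[i], to[i]] + wr[i]
      A[to[i], to[i]] <- A[to[i], to[i]] - wr[i]
    }
    A[ns, ] <- 1
    rhs <- c(rep(0, ns - 1L), 1)
    a <- tryCatch(solve(A, rhs), error = function(e2) NULL)
    if (is.null(a)) {
      stop("singular enzyme-state system in mechanism (QSSA) evaluation")
    }
    v <- 0
    for (i in prx$cat) v <- v + wf[i] * a[fr[i]] - wr[i] * a[to[i]]
  }
  if (!is.null(prx$allosteric)) {
    v <- v * mwc_factor(prx$allosteric, pp$allosteric, x)
  }
  e * v * prx$orientation
}

#' MWC regulatory factor, normalized to 1 at the reference state
#' @keywords internal
mwc_factor <- function(aplan, apars, x) {
  ti <- 1
  if (length(aplan$inh_idx)) ti <- ti + sum(x[aplan$inh_idx] / apars$K_inh)
  ta <- 1
  if (length(aplan$act_idx)) ta <- ta + sum(x[aplan$act_idx] / apars$K_act)
  Q <- apars$L * (ti / ta)^aplan$n
  (1 + apars$Q_ref) / (1 + Q)
}

#' Evaluate all reaction fluxes of a particle
#'
#' @param plan a [rate_plan()].
#' @param particle a `kinetic_particle`.
#' @param x full metabolite vector (normalized; externals at 1).
#' @param e_mult named or unnamed enzyme multipliers per reaction (default 1).
#' @return named flux vector (mmol/L-cells/h).
#' @export
network_fluxes <- function(plan, particle, x, e_mult = NULL) {
  rxns <- names(plan$reactions)
  if (is.null(e_mult)) e_mult <- rep(1, length(rxns))
  if (!is.null(names(e_mult))) e_mult <- e_mult[rxns]
  v <- numeric(length(rxns))
  for (j in seq_along(rxns)) {
    v[j] <- eval_reaction_flux(plan$reactions[[j]],
                               particle$reactions[[j]], x, e_mult[j])
  }
  names(v) <- rxns
  v
}

#' Single-reaction rate law (user-facing)
#'
#' Evaluates the flux of one reaction of a particle at given normalized
#' concentrations and enzyme level: v = e * v_catalytic(x) * f_regulatory(x).
#' At the reference state (x = 1, e = 1) this returns the reaction's
#' reference flux exactly.
#'
#' @param net network; @param ref reference state; @param particle particle.
#' @param reaction reaction id.
#' @param x named metabolite concentrations (normalized); missing entries
#'   (including externals) default to 1.
#' @param e enzyme level (default 1).
#' @export
rate_law <- function(net, ref, particle, reaction, x = NULL, e = 1) {
  plan <- rate_plan(net, ref)
  xf <- stats::setNames(rep(1, length(net$metabolites)), net$metabolites)
  if (!is.null(x)) xf[names(x)] <- x
  if (any(xf <= 0)) stop("concentrations must be strictly positive")
  if (e < 0) stop("enzyme level must be nonnegative")
  eval_reaction_flux(plan$reactions[[reaction]],
                     particle$reactions[[reaction]], xf, e)
}
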