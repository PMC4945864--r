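#' ABC rejection-sampler configuration
#'
#' @param epsilon_T overall acceptance tolerance on the weighted
#'   infinity-norm flux distance (default 0.2).
#' @param n_particles target number of accepted particles (default 1000).
#' @param weights_mode "exp" (weights = |observed flux| per dataset, i.e.
#'   pure relative error) or "ref" (weights = |reference flux|).
#' @param rng_seed integer seed; every proposal derives its own seed from it,
#'   so results are independent of how proposals are distributed over
#'   workers.
#' @param max_proposals safety cap on the number of prior draws.
#' @export
abc_config <- function(epsilon_T = 0.2, n_particles = 1000L,
                       weights_mode = c("exp", "ref"), rng_seed = 1L,
                       max_proposals = 200L * n_particles) {
  if (epsilon_T <= 0) stop("epsilon_T must be positive")
  if (n_particles < 1L) stop("n_particles must be >= 1")
  structure(list(epsilon_T = epsilon_T, n_particles = as.integer(n_particles),
                 weights_mode = match.arg(weights_mode),
                 rng_seed = as.integer(rng_seed),
                 max_proposals = as.integer(max_proposals)),
            class = "abc_config")
}

#' @keywords internal
particle_seed <- function(seed, i) {
  s <- (as.double(seed) + 48271 * as.double(i)) %% 2147483629
  as.integer(s) + 1L
}

#' Weighted infinity-norm distance between flux vectors
#'
#' max over reactions of |v_sim - v_exp| / weight; symmetric in the two flux
#' arguments. The weighting absorbs the large spread in flux magnitudes so a
#' single tolerance reads as a uniform relative error.
#'
#' @param v_sim,v_exp equal-length flux vectors.
#' @param weights positive per-reaction weights.
#' @export
flux_distance <- function(v_sim, v_exp, weights) {
  if (length(v_sim) != length(v_exp) || length(v_sim) != length(weights)) {
    stop("flux vectors and weights must have equal length")
  }
  if (any(weights <= 0)) stop("weights must be strictly positive")
  max(abs(v_sim - v_exp) / weights)
}

#' @keywords internal
dataset_weights <- function(ds, ref, mode) {
  if (mode == "ref") abs(ref$v_ref[names(ds$v_obs)]) else abs(ds$v_obs)
}

#' ABC rejection sampling of the kinetic-parameter posterior
#'
#' Repeatedly draws particles from the feasible prior, simulates the steady
#' state of every perturbation dataset, and accepts a particle only if the
#' weighted infinity-norm distance to the observed fluxes is at most
#' epsilon_T on *every* dataset. With an empty dataset list the prior is
#' returned. Steady-state solver failures count as rejections and are
#' reported separately.
#'
#' @param net network; @param ref reference state.
#' @param datasets list of `list(pert = perturbation, v_obs = named fluxes)`.
#' @param cfg an [abc_config()].
#' @param progress print progress every so many acceptances (0 = silent).
#' @return object of class `particle_set`.
#' @export
rejection_sample <- function(net, ref, datasets, cfg = abc_config(),
                             progress = 0L) {
  plan <- rate_plan(net, ref)
  n_ds <- length(datasets)
  W <- lapply(datasets, dataset_weights, ref = ref, mode = cfg$weights_mode)
  particles <- vector("list", cfg$n_particles)
  dist_mat <- matrix(NA_real_, cfg$n_particles, max(1L, n_ds))
  accepted <- 0L; proposed <- 0L; failures <- 0L
  while (accepted < cfg$n_particles && proposed < cfg$max_proposals) {
    proposed <- proposed + 1L
    set.seed(particle_seed(cfg$rng_seed, proposed))
    pt <- sample_prior_particle(net, ref, plan = plan)
    ok <- TRUE
    dists <- rep(NA_real_, max(1L, n_ds))
    if (n_ds) {
      model <- ensemble_model(net, ref, pt, plan = plan)
      for (k in seq_len(n_ds)) {
        ss <- solve_steady_state(model, datasets[[k]]$pert, fallback = FALSE)
        if (!ss$converged) { failures <- failures + 1L; ok <- FALSE; break }
        d <- flux_distance(ss$v[names(datasets[[k]]$v_obs)],
                           datasets[[k]]$v_obs, W[[k]])
        dists[k] <- d
        if (d > cfg$epsilon_T) { ok <- FALSE; break }
      }
    }
    if (ok) {
      accepted <- accepted + 1L
      particles[[accepted]] <- pt
      dist_mat[accepted, ] <- dists
      if (progress > 0L && accepted %% progress == 0L) {
        message(sprintf("accepted %d / %d (rate %.3g)", accepted,
                        cfg$n_particles, accepted / proposed))
      }
    }
  }
  particles <- particles[seq_len(accepted)]
  structure(list(particles = particles,
                 distances = dist_mat[seq_len(accepted), , drop = FALSE],
                 acceptance_rate = if (proposed) accepted / proposed else NA_real_,
                 n_proposed = proposed, solver_failures = failures,
                 underfull = accepted < cfg$n_particles,
                 config = cfg, net = net, ref = ref,
                 dataset_labels = vapply(datasets,
                                         function(d) d$pert$label, character(1))),
            class = "particle_set")
}

#' @export
print.particle_set <- function(x, ...) {
  cat("<particle_set> ", length(x$particles), " particles, acceptance rate ",
      signif(x$acceptance_rate, 3), ", ", x$solver_failures,
      " solver failures", if (x$underfull) " (UNDER-FULL)" else "", "\n",
      sep = "")
  invisible(x)
}

#' Posterior (or prior) expectancy of a functional
#'
#' Monte-Carlo mean of `functional(particle)` over a particle set, with
#' equal-tailed credible intervals. Particles on which the functional fails
#' are skipped and counted.
#'
#' @param pset a `particle_set`.
#' @param functional function(particle) -> numeric vector.
#' @param level credible level (default 0.95).
#' @export
posterior_expectancy <- function(pset, functional, level = 0.95) {
  vals <- lapply(pset$particles, function(p) {
    tryCatch(functional(p), error = function(e) NULL)
  })
  skipped <- sum(vapply(vals, is.null, logical(1)))
  vals <- vals[!vapply(vals, is.null, logical(1))]
  if (!length(vals)) stop("functional failed on every particle")
  M <- do.call(rbind, vals)
  alpha <- (1 - level) / 2
  list(mean = colMeans(M),
       lower = apply(M, 2, stats::quantile, probs = alpha, names = FALSE),
       upper = apply(M, 2, stats::quantile, probs = 1 - alpha, names = FALSE),
       sd = apply(M, 2, stats::sd),
       n_used = nrow(M), n_skipped = skipped)
}

#' Parameter-convergence diagnostics across nested training sets
#'
#' For each posterior set i, the relative Euclidean distance between the
#' posterior and prior expected parameter vectors,
#' ||E_i - E_prior|| / ||E_prior||, and the global posterior-to-prior
#' standard-deviation ratio (Euclidean norm of per-parameter standard
#' deviations).
#'
#' @param prior_set,posterior_sets `particle_set`s sharing the parameter
#'   naming.
#' @return data.frame with `set`, `expectancy_distance`, `variance_ratio`.
#' @export
convergence_metrics <- function(prior_set, posterior_sets) {
  P0 <- do.call(rbind, lapply(prior_set$particles, particle_params))
  mu0 <- colMeans(P0); sd0 <- apply(P0, 2, stats::sd)
  out <- data.frame(set = seq_along(posterior_sets),
                    expectancy_distance = NA_real_, variance_ratio = NA_real_)
  for (i in seq_along(posterior_sets)) {
    Pi <- do.call(rbind, lapply(posterior_sets[[i]]$particles, particle_params))
    if (!identical(colnames(Pi), colnames(P0))) {
      stop("parameter naming mismatch between prior and posterior set ", i)
    }
    mui <- colMeans(Pi); sdi <- apply(Pi, 2, stats::sd)
    out$expectancy_distance[i] <- sqrt(sum((mui - mu0)^2)) / sqrt(sum(mu0^2))
    out$variance_ratio[i] <- sqrt(sum(sdi^2)) / sqrt(sum(sd0^2))
  }
  out
}

#' Posterior predictive flux distributions and RMSFE
#'
#' Simulates every particle under every perturbation and summarizes the
#' predictive flux distributions (median, quartiles, central 95% interval).
#' When true responses are supplied, also returns the per-particle
#' root-mean-square flux error, RMSFE = sqrt(mean_j (v_sim_j - v_true_j)^2)
#' (mmol/L-cells/h).
#'
#' @param pset a `particle_set` (carries its network/reference).
#' @param perturbations list of [perturbation()].
#' @param truth optional list of named true flux vectors (same order).
#' @return list with `summaries` (per perturbation data.frame), `rmsfe`
#'   (matrix particles x perturbations or NULL), `failures` count.
#' @export
predict_perturbations <- function(pset, perturbations, truth = NULL) {
  plan <- rate_plan(pset$net, pset$ref)
  n_p <- length(pset$particles)
  rxns <- pset$net$reactions
  failures <- 0L
  rmsfe <- if (!is.null(truth)) {
    matrix(NA_real_, n_p, length(perturbations))
  } else NULL
  summaries <- vector("list", length(perturbations))
  names(summaries) <- vapply(perturbations, function(p) p$label, character(1))
  for (k in seq_along(perturbations)) {
    V <- matrix(NA_real_, n_p, length(rxns), dimnames = list(NULL, rxns))
    for (i in seq_len(n_p)) {
      model <- ensemble_model(pset$net, pset$ref, pset$particles[[i]], plan = plan)
      ss <- solve_steady_state(model, perturbations[[k]], fallback = FALSE)
      if (!ss$converged) { failures <- failures + 1L; next }
      V[i, ] <- ss$v[rxns]
      if (!is.null(truth)) {
        rmsfe[i, k] <- sqrt(mean((ss$v[rxns] - truth[[k]][rxns])^2))
      }
    }
    qs <- apply(V, 2, stats::quantile,
                probs = c(0.025, 0.25, 0.5, 0.75, 0.975), na.rm = TRUE)
    summaries[[k]] <- data.frame(reaction = rxns, q2.5 = qs[1, ],
                                 q25 = qs[2, ], median = qs[3, ],
                                 q75 = qs[4, ], q97.5 = qs[5, ],
                                 row.names = NULL)
  }
  list(summaries = summaries, rmsfe = rmsfe, failures = failures)
}

#' Random enzyme-level perturbations on a delta-norm hypersphere
#'
#' Marsaglia construction: independent standard-normal components per
#' reaction, normalized to Euclidean length `delta`; enzyme levels are
#' e = 1 + deltaE, floored at a small positivity floor.
#'
#' @param delta perturbation magnitude (||deltaE||_2).
#' @param n number of perturbations.
#' @param reactions character vector of perturbed reactions.
#' @param seed optional seed.
#' @param floor positivity floor on enzyme levels.
#' @return list of [perturbation()]; the number of floored components is
#'   attached as attribute `clipped`.
#' @export
random_enzyme_perturbations <- function(delta, n, reactions, seed = NULL,
                                        floor = 1e-3) {
  if (delta < 0) stop("delta must be nonnegative")
  if (!is.null(seed)) set.seed(seed)
  clipped <- 0L
  out <- vector("list", n)
  for (i in seq_len(n)) {
    z <- stats::rnorm(length(reactions))
    dE <- if (delta > 0) delta * z / sqrt(sum(z^2)) else rep(0, length(z))
    e <- 1 + dE
    clipped <- clipped + sum(e < floor)
    e <- pmax(e, floor)
    out[[i]] <- perturbation(sprintf("sphere_%g_%d", delta, i),
                             enzymes = stats::setNames(e, reactions))
    attr(out[[i]], "deltaE") <- stats::setNames(dE, reactions)
  }
  attr(out, "clipped") <- clipped
  out
}

#' Multiplicative observation noise on a flux table
#'
#' Multiplies each flux by (1 + relative_sd * z), z standard normal. Sign
#' preservation is not guaranteed for near-zero fluxes; the number of sign
#' flips is attached as attribute `sign_flips`.
#'
#' @param flux named numeric vector (or matrix) of fluxes.
#' @param relative_sd relative standard deviation (>= 0).
#' @param seed optional seed.
#' @export
add_observation_noise <- function(flux, relative_sd, seed = NULL) {
  if (relative_sd < 0) stop("relative_sd must be nonnegative")
  if (relative_sd == 0) return(flux)
  if (!is.null(seed)) set.seed(seed)
  z <- stats::rnorm(length(flux))
  out <- flux * (1 + relative_sd * z)
  attr(out, "sign_flips") <- sum(sign(out) != sign(flux) & flux != 0)
  out
}
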