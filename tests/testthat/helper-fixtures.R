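# Shared lazy fixtures (computed once per test run) and independent oracles.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

met_fixture <- function() cached("met_fixture", methionine_reference())

met_datasets <- function() cached("met_datasets", generate_datasets(seed = 1L))

met_true_fcc <- function() {
  cached("met_true_fcc", flux_control_coefficients(met_fixture()$true_model))
}

# 500-particle prior ensemble of the methionine network and its expected
# control structure (shared by several acceptance checks).
met_prior_set <- function(n = 500L) {
  cached("met_prior_set", {
    fx <- met_fixture()
    plan <- rate_plan(fx$net, fx$ref)
    particles <- lapply(seq_len(n), function(i) {
      sample_prior_particle(fx$net, fx$ref,
                            seed = kinabc:::particle_seed(1301L, i),
                            plan = plan)
    })
    structure(list(particles = particles, net = fx$net, ref = fx$ref,
                   acceptance_rate = 1, solver_failures = 0L),
              class = "particle_set")
  })
}

met_prior_fcc <- function() {
  cached("met_prior_fcc", control_structure_summary(met_prior_set()))
}

# Scaled-down posterior on training dataset #2 (the +50% influx shift).
met_posterior2 <- function() {
  cached("met_posterior2", {
    fx <- met_fixture()
    rejection_sample(fx$net, fx$ref, list(met_datasets()$training[[2]]),
                     abc_config(n_particles = 150L, rng_seed = 11L,
                                max_proposals = 60000L))
  })
}

## ---- independent King-Altman oracle -------------------------------------
## Steady-state flux by brute-force enumeration of directed spanning trees of
## the enzyme-state graph (usable for any mechanism with <= 6 states).
king_altman_flux <- function(mech, kf, kr, x, e = 1) {
  ns <- length(mech$states)
  m <- length(mech$steps)
  # directed edge list with weights
  edges <- list()
  for (i in seq_len(m)) {
    st <- mech$steps[[i]]
    wf <- kf[i] * prod(x[st$bind])
    wr <- kr[i] * prod(x[st$release])
    fr <- match(st$from, mech$states); to <- match(st$to, mech$states)
    edges[[length(edges) + 1L]] <- c(fr, to, wf, i, +1)
    edges[[length(edges) + 1L]] <- c(to, fr, wr, i, -1)
  }
  E <- do.call(rbind, edges)
  # abundance of state s ~ sum over spanning trees oriented toward s
  weight_of <- function(root) {
    total <- 0
    combs <- utils::combn(nrow(E), ns - 1L)
    for (c_i in seq_len(ncol(combs))) {
      sel <- E[combs[, c_i], , drop = FALSE]
      # each non-root state must have out-degree exactly 1, root out-degree 0
      outdeg <- tabulate(sel[, 1L], nbins = ns)
      if (outdeg[root] != 0L || any(outdeg[-root] != 1L)) next
      # no two directed edges from the same elementary step
      if (anyDuplicated(sel[, 4L])) next
      # connectivity: following the unique out-edges must reach the root
      ok <- TRUE
      for (s in seq_len(ns)[-root]) {
        cur <- s; hops <- 0L
        while (cur != root && hops <= ns) {
          nxt <- sel[sel[, 1L] == cur, 2L]
          if (!length(nxt)) { ok <- FALSE; break }
          cur <- nxt[1L]; hops <- hops + 1L
        }
        if (!ok || hops > ns) { ok <- FALSE; break }
      }
      if (ok) total <- total + prod(sel[, 3L])
    }
    total
  }
  w <- vapply(seq_len(ns), weight_of, numeric(1))
  a <- w / sum(w)
  v <- 0
  for (i in seq_len(m)) {
    st <- mech$steps[[i]]
    if (!st$catalytic) next
    wf <- kf[i] * prod(x[st$bind])
    wr <- kr[i] * prod(x[st$release])
    v <- v + wf * a[match(st$from, mech$states)] -
      wr * a[match(st$to, mech$states)]
  }
  e * v
}

# full metabolite vector at reference (normalized units)
ref_x <- function(net) {
  stats::setNames(rep(1, length(net$metabolites)), net$metabolites)
}

# Scaled-down posterior on the 10%-noise variant of dataset #2.
met_posterior2_noise10 <- function() {
  cached("met_posterior2_noise10", {
    fx <- met_fixture()
    rejection_sample(fx$net, fx$ref,
                     list(met_datasets()$training_noise10[[2]]),
                     abc_config(n_particles = 150L, rng_seed = 11L,
                                max_proposals = 120000L))
  })
}

# Pooled RMSFE distribution of a particle set over the validation design.
validation_rmsfe <- function(pset) {
  ds <- met_datasets()
  perts <- lapply(ds$validation, `[[`, "pert")
  truth <- lapply(ds$validation, `[[`, "v_obs")
  pred <- predict_perturbations(pset, perts, truth = truth)
  as.vector(pred$rmsfe[!is.na(pred$rmsfe)])
}
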