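#' Toy fixtures with analytic oracles
#'
#' Small networks (one influx, one or two drains) with closed-form steady
#' states and control coefficients, used throughout the test-suite for
#' oracle-equivalence, parameter-recovery and structure-recovery
#' experiments.
#'
#' @name toy_fixtures
NULL

#' Linear toy: influx -> A -> product
#'
#' One balanced metabolite fed by a constant boundary influx and drained by
#' a single uni-uni enzyme. The steady state solves e g(A) = b in one
#' unknown.
#' @param b influx (flux units); @param dG Gibbs energy of the drain
#'   reaction (kJ/mol).
#' @export
toy_chain <- function(b = 1, dG = -10) {
  mets <- c("A", "P")
  S <- matrix(c(-1, 1), 2, 1, dimnames = list(mets, "R1"))
  net <- metabolic_network(
    mets, S, "R1", balanced = c(TRUE, FALSE),
    boundary = list(IN = list(stoich = c(A = 1), v_ref = b)),
    mechanisms = list(R1 = mech_ordered("R1", bind = list("A"),
                                        release = list("P"))))
  ref <- reference_state(v_ref = c(R1 = b), dG_r = c(R1 = dG),
                         boundary_ref = c(IN = b),
                         x_ref = c(A = 1))
  list(net = net, ref = ref)
}

#' Branched toy: influx -> A -> two parallel drains
#'
#' Two uni-uni enzymes compete for A; optionally the second drain is under
#' planted MWC inhibition by its own substrate (used by the
#' structure-recovery experiments).
#' @param split reference flux fraction through R1.
#' @param planted_inhibition add the A -| R2 interaction to the network.
#' @export
toy_branched <- function(split = 0.6, planted_inhibition = FALSE) {
  stopifnot(is.numeric(split), split > 0, split < 1)
  mets <- c("A", "P1", "P2")
  S <- matrix(c(-1, 1, 0,
                -1, 0, 1), 3, 2, dimnames = list(mets, c("R1", "R2")))
  allo2 <- if (planted_inhibition) list(n = 2L, activators = character(),
                                        inhibitors = "A") else NULL
  net <- metabolic_network(
    mets, S, c("R1", "R2"), balanced = c(TRUE, FALSE, FALSE),
    boundary = list(IN = list(stoich = c(A = 1), v_ref = 1)),
    mechanisms = list(
      R1 = mech_ordered("R1", bind = list("A"), release = list("P1")),
      R2 = mech_ordered("R2", bind = list("A"), release = list("P2"),
                        allosteric = allo2)))
  ref <- reference_state(v_ref = c(R1 = split, R2 = 1 - split),
                         dG_r = c(R1 = -10, R2 = -12),
                         boundary_ref = c(IN = 1), x_ref = c(A = 1))
  list(net = net, ref = ref)
}

#' Random-order bi-substrate toy (no dynamics; rate-law oracle checks)
#' @export
toy_random_bi <- function() {
  mets <- c("A", "B", "C")
  S <- matrix(c(-1, -1, 1), 3, 1, dimnames = list(mets, "R1"))
  net <- metabolic_network(
    mets, S, "R1", balanced = c(FALSE, FALSE, FALSE),
    mechanisms = list(R1 = mech_random_bi("R1", subA = "A", subB = "B",
                                          release = "C")))
  ref <- reference_state(v_ref = c(R1 = 1), dG_r = c(R1 = -15),
                         boundary_ref = numeric(), x_ref = numeric())
  list(net = net, ref = ref)
}

#' Toy training data generated from a known particle
#'
#' Samples a "true" particle from the prior of the (optionally planted)
#' branched toy and simulates a set of informative perturbations.
#' @param fixture result of [toy_branched()] (or [toy_chain()]).
#' @param true_seed seed of the true particle.
#' @param perts list of perturbations; defaults to influx/enzyme shifts.
#' @return list(true_particle, datasets).
#' @export
toy_datasets <- function(fixture, true_seed = 42L, perts = NULL) {
  net <- fixture$net; ref <- fixture$ref
  true_particle <- sample_prior_particle(net, ref, seed = true_seed)
  model <- ensemble_model(net, ref, true_particle)
  if (is.null(perts)) {
    perts <- list(
      perturbation("in_up", boundary = c(IN = 1.15)),
      perturbation("in_dn", boundary = c(IN = 0.7)),
      perturbation("e1_up", enzymes = c(R1 = 1.5)),
      perturbation("e2_dn", enzymes = stats::setNames(
        0.6, net$reactions[length(net$reactions)])))
  }
  datasets <- lapply(perts, function(pt) {
    ss <- solve_steady_state(model, pt)
    if (!ss$converged) stop("toy perturbation '", pt$label, "' did not converge")
    list(pert = pt, v_obs = ss$v, weights = abs(ss$v))
  })
  list(true_particle = true_particle, datasets = datasets)
}
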