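#' Add a candidate allosteric interaction to a network
#'
#' Returns a copy of the network whose mechanism for `enzyme` carries the
#' extra effector (activator or inhibitor, exclusive MWC binding). Enzymes
#' without an allosteric specification acquire one with `n_subunits`
#' subunits.
#'
#' @param net a `metabolic_network`.
#' @param enzyme reaction id.
#' @param effector metabolite id (must belong to the network).
#' @param sign "activation" or "inhibition".
#' @param n_subunits subunit count used when the enzyme had no allosteric
#'   specification yet.
#' @export
add_interaction <- function(net, enzyme, effector,
                            sign = c("activation", "inhibition"),
                            n_subunits = 2L) {
  sign <- match.arg(sign)
  if (!enzyme %in% net$reactions) stop("unknown enzyme '", enzyme, "'")
  if (!effector %in% net$metabolites) {
    stop("effector '", effector, "' is not a network metabolite")
  }
  mech <- net$mechanisms[[enzyme]]
  al <- mech$allosteric %||% list(n = n_subunits, activators = character(),
                                  inhibitors = character())
  if (effector %in% c(al$activators, al$inhibitors)) {
    stop("interaction ", enzyme, " <- ", effector, " already present")
  }
  if (sign == "activation") al$activators <- c(al$activators, effector)
  else al$inhibitors <- c(al$inhibitors, effector)
  net$mechanisms[[enzyme]] <- reaction_mechanism(
    mech$name, mech$states, mech$steps, mech$routes, allosteric = al)
  net
}

#' Enumerate single-addition structure candidates
#'
#' Base structure plus one structure per candidate interaction, in input
#' order (deterministic).
#'
#' @param base_net the reference (possibly incomplete) network.
#' @param candidates list of `list(enzyme=, effector=, sign=)`.
#' @return named list of networks; first element `base`.
#' @export
enumerate_structures <- function(base_net, candidates) {
  out <- list(base = base_net)
  for (cd in candidates) {
    lab <- sprintf("%s<-%s(%s)", cd$enzyme, cd$effector,
                   if (cd$sign == "activation") "+" else "-")
    if (lab %in% names(out)) stop("duplicate candidate ", lab)
    out[[lab]] <- add_interaction(base_net, cd$enzyme, cd$effector, cd$sign,
                                  n_subunits = cd$n_subunits %||% 2L)
  }
  out
}

#' ABC model choice over allosteric structures
#'
#' Each proposal first draws a structure index uniformly, then a prior
#' particle for that structure, and applies the standard per-dataset
#' epsilon_T acceptance. Marginal model probabilities are the normalized
#' acceptance counts; Bayes factors are count ratios against the first
#' (reference) structure. Significance combines the Bayes-factor >= 3 rule
#' with an exact one-sided binomial test of the top structure's count
#' against the uniform-acceptance null.
#'
#' @param structures named list of networks (first = reference structure).
#' @param ref shared [reference_state()].
#' @param datasets training datasets (as in [rejection_sample()]).
#' @param cfg an [abc_config()] (`n_particles` = total accepted budget).
#' @param bf_threshold Bayes-factor significance threshold (default 3).
#' @return object of class `selection_result`.
#' @export
abc_model_choice <- function(structures, ref, datasets, cfg = abc_config(),
                             bf_threshold = 3) {
  k <- length(structures)
  if (k < 2L) stop("need at least two structures")
  plans <- lapply(structures, rate_plan, ref = ref)
  W <- lapply(datasets, dataset_weights, ref = ref, mode = cfg$weights_mode)
  counts <- stats::setNames(integer(k), names(structures))
  accepted <- 0L; proposed <- 0L; failures <- 0L
  while (accepted < cfg$n_particles && proposed < cfg$max_proposals) {
    proposed <- proposed + 1L
    set.seed(particle_seed(cfg$rng_seed, proposed))
    m <- sample.int(k, 1L)
    pt <- sample_prior_particle(structures[[m]], ref, plan = plans[[m]],
                                structure_index = m - 1L)
    ok <- TRUE
    model <- ensemble_model(structures[[m]], ref, pt, plan = plans[[m]])
    for (j in seq_along(datasets)) {
      ss <- solve_steady_state(model, datasets[[j]]$pert, fallback = FALSE)
      if (!ss$converged) { failures <- failures + 1L; ok <- FALSE; break }
      d <- flux_distance(ss$v[names(datasets[[j]]$v_obs)],
                         datasets[[j]]$v_obs, W[[j]])
      if (d > cfg$epsilon_T) { ok <- FALSE; break }
    }
    if (ok) { accepted <- accepted + 1L; counts[m] <- counts[m] + 1L }
  }
  probs <- if (accepted) counts / accepted else counts * NA_real_
  bf <- if (counts[1L] > 0) counts / counts[1L] else
    ifelse(counts > 0, Inf, NA_real_)
  top <- which.max(counts)
  p_top <- stats::binom.test(counts[top], accepted, p = 1 / k,
                             alternative = "greater")$p.value
  structure(list(counts = counts, marginal_probabilities = probs,
                 bayes_factors = bf,
                 significant = bf >= bf_threshold & seq_len(k) != 1L,
                 p_value_top = p_top, top = names(structures)[top],
                 n_accepted = accepted, n_proposed = proposed,
                 acceptance_rate = accepted / max(1L, proposed),
                 solver_failures = failures),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result> accepted", x$n_accepted, "of", x$n_proposed,
      "proposals\n")
  print(data.frame(structure = names(x$counts), count = as.integer(x$counts),
                   probability = round(x$marginal_probabilities, 3),
                   bayes_factor = round(x$bayes_factors, 2)))
  cat("top:", x$top, " binomial p =", signif(x$p_value_top, 3), "\n")
  invisible(x)
}

#' Greedy one-at-a-time interaction search
#'
#' Repeatedly runs [abc_model_choice()] over the remaining candidates,
#' permanently adds the most probable interaction whose Bayes factor against
#' the current reference structure reaches the threshold, and stops when no
#' candidate is significantly enriched.
#'
#' @inheritParams abc_model_choice
#' @param base_net starting (incomplete) network.
#' @param candidates candidate interaction list (see
#'   [enumerate_structures()]).
#' @return list with `additions` (labels in acceptance order), `history`
#'   (selection results per round), `final_net`.
#' @export
greedy_interaction_search <- function(base_net, ref, candidates, datasets,
                                      cfg = abc_config(), bf_threshold = 3) {
  additions <- character(0)
  history <- list()
  net <- base_net
  remaining <- candidates
  round <- 0L
  while (length(remaining)) {
    round <- round + 1L
    cfg_round <- cfg
    cfg_round$rng_seed <- particle_seed(cfg$rng_seed, 10000L * round)
    structures <- enumerate_structures(net, remaining)
    res <- abc_model_choice(structures, ref, datasets, cfg_round, bf_threshold)
    history[[round]] <- res
    cand_idx <- which(res$significant)
    if (!length(cand_idx)) break
    best <- cand_idx[which.max(res$counts[cand_idx])]
    lab <- names(res$counts)[best]
    pick <- remaining[[best - 1L]]
    net <- add_interaction(net, pick$enzyme, pick$effector, pick$sign,
                           n_subunits = pick$n_subunits %||% 2L)
    additions <- c(additions, lab)
    remaining <- remaining[-(best - 1L)]
  }
  list(additions = additions, history = history, final_net = net)
}
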