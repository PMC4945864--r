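#' Elementary-step reaction mechanisms
#'
#' A `reaction_mechanism` is a small directed graph over enzyme states (free
#' enzyme, substrate/product complexes). Each elementary step connects two
#' states and may bind or release metabolites; exactly the steps flagged
#' `catalytic` interconvert bound substrate into bound product. One or more
#' *routes* (ordered step sequences from the free enzyme back to itself)
#' describe how catalysis proceeds; random-order mechanisms have several
#' routes sharing their catalytic segment.
#'
#' @param name mechanism identifier (usually the reaction id).
#' @param states character vector of enzyme-state identifiers; the first is
#'   taken as the free enzyme.
#' @param steps list of steps created with [mech_step()].
#' @param routes list of integer vectors; each vector lists the step indices
#'   traversed (in their forward orientation) along one catalytic route.
#' @param allosteric optional list with elements `n` (number of subunits),
#'   `activators` and `inhibitors` (character vectors of metabolite ids).
#' @return an object of class `reaction_mechanism`.
#' @export
reaction_mechanism <- function(name, states, steps, routes,
                               allosteric = NULL) {
  stopifnot(is.character(states), length(states) >= 2L)
  if (anyDuplicated(states)) stop("duplicate enzyme state identifiers in '", name, "'")
  for (s in steps) {
    if (!all(c(s$from, s$to) %in% states)) {
      stop("step references unknown state in mechanism '", name, "'")
    }
  }
  if (!length(routes)) stop("mechanism '", name, "' declares no route")
  routes <- lapply(routes, as.integer)
  for (r in routes) {
    if (any(r < 1L | r > length(steps))) {
      stop("route references unknown step in mechanism '", name, "'")
    }
  }
  if (!is.null(allosteric)) {
    allosteric$n <- as.integer(allosteric$n %||% 1L)
    if (allosteric$n < 1L) stop("allosteric subunit count must be positive")
    allosteric$activators <- as.character(allosteric$activators %||% character())
    allosteric$inhibitors <- as.character(allosteric$inhibitors %||% character())
  }
  mech <- structure(
    list(name = name, states = states, steps = steps, routes = routes,
         allosteric = allosteric),
    class = "reaction_mechanism")
  validate_mechanism(mech)
  mech
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Create one elementary step
#'
#' @param from,to enzyme-state identifiers.
#' @param bind metabolites bound in the forward direction (character vector;
#'   lumped co-binding is allowed).
#' @param release metabolites released in the forward direction.
#' @param catalytic logical; `TRUE` for the chemistry step.
#' @export
mech_step <- function(from, to, bind = character(), release = character(),
                      catalytic = FALSE) {
  list(from = from, to = to, bind = as.character(bind),
       release = as.character(release), catalytic = isTRUE(catalytic))
}

#' @keywords internal
validate_mechanism <- function(mech) {
  ## connectivity of the state graph
  adj <- matrix(FALSE, length(mech$states), length(mech$states),
                dimnames = list(mech$states, mech$states))
  for (s in mech$steps) adj[s$from, s$to] <- adj[s$to, s$from] <- TRUE
  seen <- mech$states[1L]
  repeat {
    nxt <- unique(unlist(lapply(seen, function(v) mech$states[adj[v, ]])))
    new <- setdiff(nxt, seen)
    if (!length(new)) break
    seen <- c(seen, new)
  }
  if (length(seen) != length(mech$states)) {
    stop("enzyme-state graph of mechanism '", mech$name, "' is not connected")
  }
  ## every route must close on the free enzyme and share one net stoichiometry
  net0 <- NULL
  for (r in mech$routes) {
    at <- mech$states[1L]
    for (i in r) {
      st <- mech$steps[[i]]
      if (st$from != at) {
        stop("route of mechanism '", mech$name,
             "' is not a contiguous forward walk")
      }
      at <- st$to
    }
    if (at != mech$states[1L]) {
      stop("route of mechanism '", mech$name, "' does not return to free enzyme")
    }
    if (sum(vapply(mech$steps[r], function(s) s$catalytic, logical(1))) != 1L) {
      stop("route of mechanism '", mech$name,
           "' must contain exactly one catalytic step")
    }
    net <- route_net_stoich(mech, r)
    if (is.null(net0)) net0 <- net
    else if (!identical(net0[order(names(net0))], net[order(names(net))])) {
      stop("routes of mechanism '", mech$name,
           "' have inconsistent net stoichiometry")
    }
  }
  invisible(mech)
}

#' Net metabolite stoichiometry of one route (consumed < 0, produced > 0)
#' @keywords internal
route_net_stoich <- function(mech, route) {
  net <- numeric(0)
  bump <- function(net, m, d) {
    for (x in m) net[x] <- (if (x %in% names(net)) net[x] else 0) + d
    net
  }
  for (i in route) {
    st <- mech$steps[[i]]
    net <- bump(net, st$bind, -1)
    net <- bump(net, st$release, +1)
  }
  net[net != 0]
}

#' Ordered (compulsory-order) mechanism builder
#'
#' Builds a linear catalytic cycle: substrates bind in the given order, one
#' catalytic step converts the fully loaded complex, products are released in
#' the given order. Each element of `bind`/`release` is a character vector of
#' metabolites handled in that single elementary step (lumped co-binding).
#'
#' @param name mechanism id.
#' @param bind list of character vectors (binding steps, in order).
#' @param release list of character vectors (release steps, in order).
#' @param allosteric optional allosteric specification (see
#'   [reaction_mechanism()]).
#' @export
mech_ordered <- function(name, bind, release, allosteric = NULL) {
  if (is.character(bind)) bind <- list(bind)
  if (is.character(release)) release <- list(release)
  nb <- length(bind); nr <- length(release)
  n_states <- nb + nr + 1L
  states <- c("E", paste0("E", seq_len(nb + nr)))
  steps <- list()
  for (i in seq_len(nb)) {
    steps[[length(steps) + 1L]] <-
      mech_step(states[i], states[i + 1L], bind = bind[[i]])
  }
  steps[[length(steps) + 1L]] <-
    mech_step(states[nb + 1L], states[nb + 2L], catalytic = TRUE)
  for (i in seq_len(nr)) {
    to <- if (i == nr) states[1L] else states[nb + 1L + i + 1L]
    steps[[length(steps) + 1L]] <-
      mech_step(states[nb + 1L + i], to, release = release[[i]])
  }
  reaction_mechanism(name, states[seq_len(n_states)], steps,
                     routes = list(seq_along(steps)), allosteric = allosteric)
}

#' Random-order bi-substrate mechanism builder
#'
#' Two substrates bind in either order (four binding steps over a diamond of
#' states), followed by a shared catalytic step and a single lumped release
#' step. The two routes share the catalytic segment; flux is split between
#' them by the sampled branching fractions.
#'
#' @param name mechanism id.
#' @param subA,subB the two substrates.
#' @param release character vector of products released in the lumped step.
#' @param allosteric optional allosteric specification.
#' @export
mech_random_bi <- function(name, subA, subB, release, allosteric = NULL) {
  states <- c("E", "EA", "EB", "EAB", "EPQ")
  steps <- list(
    mech_step("E", "EA", bind = subA),      # 1: A first
    mech_step("EA", "EAB", bind = subB),    # 2
    mech_step("E", "EB", bind = subB),      # 3: B first
    mech_step("EB", "EAB", bind = subA),    # 4
    mech_step("EAB", "EPQ", catalytic = TRUE), # 5 shared
    mech_step("EPQ", "E", release = release)   # 6 shared
  )
  reaction_mechanism(name, states, steps,
                     routes = list(c(1L, 2L, 5L, 6L), c(3L, 4L, 5L, 6L)),
                     allosteric = allosteric)
}

#' Number of kinetic parameters of a mechanism
#'
#' Two scaled rate constants per elementary step, plus the allosteric constant
#' L and one effector constant per declared effector for allosteric enzymes.
#' @param mech a `reaction_mechanism`.
#' @export
n_parameters <- function(mech) {
  n <- 2L * length(mech$steps)
  if (!is.null(mech$allosteric)) {
    n <- n + 1L + length(mech$allosteric$activators) +
      length(mech$allosteric$inhibitors)
  }
  n
}

#' Reverse the orientation of a mechanism (used when the reference flux of a
#' reaction is negative: sampling always proceeds along the net direction).
#' @keywords internal
flip_mechanism <- function(mech) {
  steps <- lapply(mech$steps, function(s) {
    mech_step(s$to, s$from, bind = s$release, release = s$bind,
              catalytic = s$catalytic)
  })
  routes <- lapply(mech$routes, function(r) rev(r))
  reaction_mechanism(mech$name, mech$states, steps, routes,
                     allosteric = mech$allosteric)
}

#' @export
print.reaction_mechanism <- function(x, ...) {
  cat("<reaction_mechanism> ", x$name, ": ", length(x$states), " states, ",
      length(x$steps), " steps, ", length(x$routes), " route(s)",
      if (!is.null(x$allosteric)) sprintf(", MWC n=%d", x$allosteric$n) else "",
      "\n", sep = "")
  invisible(x)
}
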