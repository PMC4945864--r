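#' Read and write perturbation datasets as delimited text
#'
#' The external representation uses two TSV tables: a perturbation table
#' with columns `label`, `target`, `type` ("enzyme" or "boundary") and
#' `multiplier`, and an observation table with columns `label`, `reaction`,
#' `flux` (mmol/L-cells/h).
#'
#' @param datasets list of `list(pert, v_obs)` entries.
#' @param pert_file,obs_file output/input paths.
#' @export
write_datasets <- function(datasets, pert_file, obs_file) {
  pr <- do.call(rbind, lapply(datasets, function(d) {
    rows <- NULL
    if (length(d$pert$enzymes)) {
      rows <- rbind(rows, data.frame(label = d$pert$label,
                                     target = names(d$pert$enzymes),
                                     type = "enzyme",
                                     multiplier = unname(d$pert$enzymes)))
    }
    if (length(d$pert$boundary)) {
      rows <- rbind(rows, data.frame(label = d$pert$label,
                                     target = names(d$pert$boundary),
                                     type = "boundary",
                                     multiplier = unname(d$pert$boundary)))
    }
    rows
  }))
  ob <- do.call(rbind, lapply(datasets, function(d) {
    data.frame(label = d$pert$label, reaction = names(d$v_obs),
               flux = unname(d$v_obs))
  }))
  utils::write.table(pr, pert_file, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ob, obs_file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(pert_file, obs_file))
}

#' @rdname write_datasets
#' @export
read_datasets <- function(pert_file, obs_file) {
  pr <- utils::read.delim(pert_file, stringsAsFactors = FALSE)
  ob <- utils::read.delim(obs_file, stringsAsFactors = FALSE)
  labels <- unique(pr$label)
  lapply(labels, function(lb) {
    rows <- pr[pr$label == lb, , drop = FALSE]
    enz <- rows[rows$type == "enzyme", ]
    bnd <- rows[rows$type == "boundary", ]
    pt <- perturbation(lb,
                       enzymes = stats::setNames(enz$multiplier, enz$target),
                       boundary = stats::setNames(bnd$multiplier, bnd$target))
    o <- ob[ob$label == lb, , drop = FALSE]
    list(pert = pt, v_obs = stats::setNames(o$flux, o$reaction),
         weights = abs(stats::setNames(o$flux, o$reaction)))
  })
}

#' Export a network (ordered mechanisms only) as a YAML model spec
#'
#' Produces the structured model document read back by [load_network()].
#' @param net a `metabolic_network`.
#' @param file output path.
#' @export
write_model_spec <- function(net, file) {
  mech_spec <- function(mech) {
    cat_i <- which(vapply(mech$steps, `[[`, logical(1), "catalytic"))
    if (length(mech$routes) != 1L) {
      stop("YAML export supports single-route (ordered) mechanisms only")
    }
    bind <- lapply(mech$steps[seq_len(cat_i - 1L)], `[[`, "bind")
    release <- lapply(mech$steps[seq(cat_i + 1L, length(mech$steps))],
                      `[[`, "release")
    list(kind = "ordered", bind = bind, release = release)
  }
  rxs <- lapply(net$reactions, function(rx) {
    col <- net$S[, rx]
    entry <- list(id = rx, stoichiometry = as.list(col[col != 0]),
                  mechanism = mech_spec(net$mechanisms[[rx]]))
    al <- net$mechanisms[[rx]]$allosteric
    if (!is.null(al)) {
      entry$allosteric <- list(n = al$n,
                               activators = as.list(al$activators),
                               inhibitors = as.list(al$inhibitors))
    }
    entry
  })
  doc <- list(
    metabolites = lapply(seq_along(net$metabolites), function(i) {
      m <- list(id = net$metabolites[i])
      if (!net$balanced[i]) m$external <- TRUE
      m
    }),
    reactions = rxs,
    boundary = lapply(names(net$boundary), function(b) {
      list(id = b, stoichiometry = as.list(net$boundary[[b]]$stoich),
           v_ref = net$boundary[[b]]$v_ref)
    }),
    pools = lapply(net$pools, function(p) {
      list(members = as.list(p$members), total = p$total)
    }))
  yaml::write_yaml(doc, file)
  invisible(file)
}

#' Write Gibbs free energy ranges as a delimited table
#' @param ranges result of [gibbs_ranges()]; @param file output path.
#' @export
write_gibbs_ranges <- function(ranges, file) {
  utils::write.table(as.data.frame(ranges), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
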