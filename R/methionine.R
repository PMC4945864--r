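#' The bundled mammalian methionine-cycle fixture
#'
#' A synthetic reconstruction of a detailed kinetic reference model of the
#' mammalian methionine cycle, used as the "true model" that generates all
#' training and validation data in this package. Rate-law forms follow the
#' classical literature descriptions of this pathway (saturable
#' Michaelis-Menten/Hill kinetics, AdoMet feedback inhibition of MATI and
#' activation of MATIII and CBS, cooperative GNMT inhibited by AdoHcy and
#' 5-CH3-THF, AdoMet inhibition of MTHFR, reversible rapid-equilibrium AHC);
#' the parameter values are this package's own choices, tuned only so that
#' the model has a stable physiological steady state with a methionine
#' uptake of 0.76 mmol/L-cells/h and an approximately 22-fold spread between
#' the largest and smallest cycle flux. It is NOT a transcription of any
#' published parameter set.
#'
#' The network couples six balanced intermediates (Met, AdoMet, AdoHcy, Hcy,
#' 5-CH3-THF, 5,10-CH2-THF; the last two form a conserved folate pool)
#' through nine enzymatic reactions, with methionine influx and protein
#' turnover as boundary fluxes.
#'
#' @name methionine_fixture
NULL

MET_REACTIONS <- c("MATI", "MATIII", "GNMT", "METH", "AHC",
                   "BHMT", "MS", "MTHFR", "CBS")

#' Parameters of the synthetic true model (43 in total)
#' @keywords internal
methionine_true_params <- function() {
  list(
    influx = 0.76,                                    # mmol/L-cells/h
    prot = c(Vm = NA, Km = 0.002),
    MATI = c(Vm = NA, Km = 0.04, Ki = 0.05, f = 0.2),
    MATIII = c(Vm = NA, Kma = 0.3, Kmb = 0.3, a = 5, Ka = 0.06, h = 2),
    GNMT = c(Vm = NA, Km = 0.08, nH = 2.3, Ki_ahcy = 0.004,
             Ki_mthf = 0.002, f = 0.15),
    METH = c(Vm = NA, Km = 0.01, Ki = 0.004),
    AHC = c(Vm = NA, Keq = 7.4236e-3, Ka = 0.004, Kp = 0.002, ade = 0.001),
    BHMT = c(Vm = NA, Km = 0.002, b = 8),
    MS = c(Vm = NA, Km_hcy = 0.001, Km_mthf = 0.002),
    MTHFR = c(Vm = NA, Km = 0.001, Ki = 0.05, nI = 2),
    CBS = c(Vm = NA, Km = 0.003, a = 4, Ka = 0.07, nA = 2),
    folate_total = 0.003                              # mmol/L
  )
}

#' Reference concentrations (mmol/L) and target reference fluxes
#' @keywords internal
methionine_reference_point <- function() {
  list(
    x = c(Met = 0.050, AdoMet = 0.060, AdoHcy = 0.003, Hcy = 0.001,
          MTHF = 0.002, CH2THF = 0.001),
    v = c(MATI = 0.45, MATIII = 0.43, GNMT = 0.33, METH = 0.55, AHC = 0.88,
          BHMT = 0.20, MS = 0.04, MTHFR = 0.04, CBS = 0.64),
    vb = c(INFLUX = 0.76, PROT = 0.12))
}

#' Shape factors of the true rate laws (flux per unit Vm)
#' @keywords internal
methionine_true_shapes <- function(x, p) {
  Met <- x[["Met"]]; AdoMet <- x[["AdoMet"]]; AdoHcy <- x[["AdoHcy"]]
  Hcy <- x[["Hcy"]]; MTHF <- x[["MTHF"]]; CH2THF <- x[["CH2THF"]]
  q <- numeric(0)
  pm <- p$MATI
  q["MATI"] <- Met / (pm[["Km"]] + Met) *
    (pm[["f"]] + (1 - pm[["f"]]) * pm[["Ki"]] / (pm[["Ki"]] + AdoMet))
  pm <- p$MATIII
  act <- (1 + pm[["a"]] * AdoMet^pm[["h"]] / (pm[["Ka"]]^pm[["h"]] + AdoMet^pm[["h"]])) /
    (1 + pm[["a"]])
  q["MATIII"] <- Met^2 / (pm[["Kma"]] * pm[["Kmb"]] + pm[["Kmb"]] * Met + Met^2) * act
  pm <- p$GNMT
  q["GNMT"] <- 1 / (1 + (pm[["Km"]] / AdoMet)^pm[["nH"]]) *
    (pm[["f"]] + (1 - pm[["f"]]) * pm[["Ki_ahcy"]] / (pm[["Ki_ahcy"]] + AdoHcy)) *
    pm[["Ki_mthf"]] / (pm[["Ki_mthf"]] + MTHF)
  pm <- p$METH
  q["METH"] <- 1 / (1 + (pm[["Km"]] / AdoMet) * (1 + AdoHcy / pm[["Ki"]]))
  pm <- p$AHC
  q["AHC"] <- (AdoHcy - Hcy * pm[["ade"]] / pm[["Keq"]]) /
    (pm[["Ka"]] + AdoHcy + (pm[["Ka"]] / pm[["Kp"]]) * Hcy)
  pm <- p$BHMT
  q["BHMT"] <- Hcy / (pm[["Km"]] + Hcy) * exp(-pm[["b"]] * (AdoMet + AdoHcy))
  pm <- p$MS
  q["MS"] <- Hcy * MTHF / ((pm[["Km_hcy"]] + Hcy) * (pm[["Km_mthf"]] + MTHF))
  pm <- p$MTHFR
  q["MTHFR"] <- CH2THF / (pm[["Km"]] + CH2THF) *
    pm[["Ki"]]^pm[["nI"]] / (pm[["Ki"]]^pm[["nI"]] + AdoMet^pm[["nI"]])
  pm <- p$CBS
  q["CBS"] <- Hcy / (pm[["Km"]] + Hcy) *
    (1 + pm[["a"]] * AdoMet^pm[["nA"]] / (pm[["Ka"]]^pm[["nA"]] + AdoMet^pm[["nA"]])) /
    (1 + pm[["a"]])
  q
}

#' Build the synthetic methionine-cycle true model
#'
#' Maximal rates are calibrated so that the declared reference concentrations
#' are an exact steady state carrying the target reference flux distribution
#' (v_INFLUX = 0.76 mmol/L-cells/h).
#'
#' @return a [kinetic_model()] operating on absolute concentrations
#'   (mmol/L); the parameter list is attached as attribute `params`.
#' @export
build_true_model <- function() {
  p <- methionine_true_params()
  rp <- methionine_reference_point()
  shapes <- methionine_true_shapes(rp$x, p)
  for (rx in MET_REACTIONS) p[[rx]][["Vm"]] <- rp$v[[rx]] / shapes[[rx]]
  p$prot[["Vm"]] <- rp$vb[["PROT"]] /
    (rp$x[["Met"]] / (p$prot[["Km"]] + rp$x[["Met"]]))
  net <- methionine_network()
  ref <- reference_state(
    v_ref = rp$v, dG_r = methionine_dG_targets(),
    boundary_ref = rp$vb, x_ref = rp$x)
  flux_fun <- function(x_bal, e_mult, b_mult, b_add) {
    v <- methionine_true_shapes(x_bal, p)
    for (rx in MET_REACTIONS) v[[rx]] <- v[[rx]] * p[[rx]][["Vm"]]
    v <- v * e_mult[MET_REACTIONS]
    vb <- c(INFLUX = p$influx * b_mult[["INFLUX"]] + b_add[["INFLUX"]],
            PROT = p$prot[["Vm"]] * x_bal[["Met"]] /
              (p$prot[["Km"]] + x_bal[["Met"]]) * b_mult[["PROT"]] +
              b_add[["PROT"]])
    list(v = v, vb = vb)
  }
  model <- kinetic_model(net, ref, flux_fun,
                         conc_scale = stats::setNames(rep(1, 6), names(rp$x)),
                         x0 = rp$x, label = "methionine_true_synthetic")
  attr(model, "params") <- p
  model
}

#' Count of scalar parameters of the true model
#' @export
true_model_parameter_count <- function() {
  p <- methionine_true_params()
  sum(vapply(p, length, integer(1)))
}

#' The methionine-cycle network with its detailed mechanisms
#'
#' Nine enzymatic reactions with elementary-step mechanisms (compulsory-order
#' binding; lumped co-substrate binding for clamped externals) and MWC
#' allosteric specifications for the five regulated enzymes, plus methionine
#' influx and protein turnover as boundary fluxes. The detailed
#' parameterization over this network has 72 kinetic parameters.
#'
#' @param gnmt_effectors inhibitors of GNMT in the detailed structure
#'   (default 5-CH3-THF).
#' @param matiii_activators activators of MATIII (default AdoMet).
#' @export
methionine_network <- function(gnmt_effectors = "MTHF",
                               matiii_activators = "AdoMet") {
  mets <- c("Met", "AdoMet", "AdoHcy", "Hcy", "MTHF", "CH2THF",
            "MGA", "MGACH3", "Ade", "Bet", "DMG", "Cysta")
  balanced <- c(rep(TRUE, 6), rep(FALSE, 6))
  rxns <- MET_REACTIONS
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  S["Met", c("MATI", "MATIII")] <- -1
  S["AdoMet", c("MATI", "MATIII")] <- 1
  S["AdoMet", c("GNMT", "METH")] <- -1
  S["AdoHcy", c("GNMT", "METH")] <- 1
  S["AdoHcy", "AHC"] <- -1
  S["Hcy", "AHC"] <- 1
  S["Hcy", c("BHMT", "MS", "CBS")] <- -1
  S["Met", c("BHMT", "MS")] <- 1
  S["MTHF", "MS"] <- -1
  S["CH2THF", "MS"] <- 1
  S["CH2THF", "MTHFR"] <- -1
  S["MTHF", "MTHFR"] <- 1
  S["MGA", "METH"] <- -1; S["MGACH3", "METH"] <- 1
  S["Ade", "AHC"] <- 1
  S["Bet", "BHMT"] <- -1; S["DMG", "BHMT"] <- 1
  S["Cysta", "CBS"] <- 1

  allo <- function(n, act = NULL, inh = NULL) {
    list(n = n, activators = act, inhibitors = inh)
  }
  mechanisms <- list(
    MATI = mech_ordered("MATI", bind = list("Met"), release = list("AdoMet"),
                        allosteric = allo(2, inh = "AdoMet")),
    MATIII = mech_ordered("MATIII", bind = list("Met"), release = list("AdoMet"),
                          allosteric = if (length(matiii_activators))
                            allo(2, act = matiii_activators) else NULL),
    GNMT = mech_ordered("GNMT", bind = list("AdoMet"), release = list("AdoHcy"),
                        allosteric = if (length(gnmt_effectors))
                          allo(4, inh = gnmt_effectors) else NULL),
    METH = mech_ordered("METH", bind = list("AdoMet", "MGA"),
                        release = list(c("AdoHcy", "MGACH3"))),
    AHC = mech_ordered("AHC", bind = list("AdoHcy"),
                       release = list("Ade", "Hcy")),
    BHMT = mech_ordered("BHMT", bind = list("Hcy", "Bet"),
                        release = list(c("DMG", "Met"))),
    MS = mech_ordered("MS", bind = list("MTHF", "Hcy"),
                      release = list(c("Met", "CH2THF"))),
    MTHFR = mech_ordered("MTHFR", bind = list("CH2THF"), release = list("MTHF"),
                         allosteric = allo(2, inh = "AdoMet")),
    CBS = mech_ordered("CBS", bind = list("Hcy"), release = list("Cysta"),
                       allosteric = allo(2, act = "AdoMet"))
  )
  metabolic_network(
    mets, S, rxns, balanced = balanced,
    boundary = list(INFLUX = list(stoich = c(Met = 1), v_ref = 0.76),
                    PROT = list(stoich = c(Met = -1), v_ref = 0.12)),
    pools = list(list(members = c("MTHF", "CH2THF"), total = 0.003)),
    mechanisms = mechanisms)
}

#' Reference Gibbs free energies targeted by the thermodynamic fixture
#' (kJ/mol at the reference concentrations)
#' @keywords internal
methionine_dG_targets <- function() {
  c(MATI = -40, MATIII = -40, GNMT = -30, METH = -12, AHC = -8,
    BHMT = -10, MS = -4, MTHFR = -22, CBS = -3)
}

#' Thermodynamic input of the methionine fixture
#'
#' Standard Gibbs free energies (external/clamped species folded in) and
#' concentration bounds spanning a factor of 30 either side of the reference
#' concentrations. Values are synthetic (chosen to reflect the known strong
#' driving force of the MAT and methyl-transfer steps and the
#' near-equilibrium operation of CBS and MS).
#'
#' @param spread multiplicative half-width of the concentration bounds.
#' @param RT kJ/mol.
#' @export
methionine_thermo <- function(spread = 30, RT = 2.5787) {
  net <- methionine_network()
  rp <- methionine_reference_point()
  lnx <- log(rp$x)
  Sb <- S_balanced(net)
  targets <- methionine_dG_targets()
  dG0 <- targets - RT * drop(crossprod(Sb, lnx))
  thermo_input(dG0_r = stats::setNames(dG0, net$reactions),
               ln_x_min = lnx - log(spread), ln_x_max = lnx + log(spread),
               v_ref_signs = stats::setNames(rep(1, length(net$reactions)),
                                             net$reactions),
               RT = RT)
}

#' Assembled reference data of the methionine fixture
#'
#' Solves the true model's steady state, runs the thermodynamic variability
#' analysis and returns the network, reference state (v_ref, midpoint dG_r,
#' x_ref) and Gibbs ranges used by the detailed parameterization.
#' @param ... passed to [methionine_network()] (structure variants).
#' @export
methionine_reference <- function(...) {
  true <- build_true_model()
  ss <- solve_steady_state(true)
  if (!ss$converged) stop("true model failed to reach its reference steady state")
  net <- methionine_network(...)
  thermo <- methionine_thermo()
  ranges <- gibbs_ranges(net, thermo)
  dG <- reference_dG(ranges)
  ref <- reference_state(v_ref = ss$v, dG_r = dG,
                         boundary_ref = ss$v_boundary, x_ref = ss$x,
                         RT = thermo$RT)
  validate_reference_state(net, ref, tol = 1e-6)
  list(net = net, ref = ref, thermo = thermo, ranges = ranges,
       true_model = true, reference_steady_state = ss)
}

#' Training and validation perturbation designs
#'
#' Twelve one-at-a-time training perturbations (+50% on each enzyme and on
#' the two boundary fluxes, with the second entry the +50% methionine-influx
#' shift, plus one stronger influx shift) and the twelve opposite-direction
#' counterparts of the same magnitude as validation.
#' @return list with elements `training` and `validation` (lists of
#'   [perturbation()]).
#' @export
methionine_perturbations <- function() {
  up <- 1.5
  mk <- function(label, enzymes = numeric(), boundary = numeric()) {
    perturbation(label, enzymes = enzymes, boundary = boundary)
  }
  targets <- list(
    list(id = "MATI", type = "enzyme"), list(id = "INFLUX", type = "boundary"),
    list(id = "MATIII", type = "enzyme"), list(id = "GNMT", type = "enzyme"),
    list(id = "METH", type = "enzyme"), list(id = "AHC", type = "enzyme"),
    list(id = "BHMT", type = "enzyme"), list(id = "MS", type = "enzyme"),
    list(id = "MTHFR", type = "enzyme"), list(id = "CBS", type = "enzyme"),
    list(id = "PROT", type = "boundary"),
    list(id = "INFLUX", type = "boundary", mult = 1.8))
  build <- function(direction) {
    out <- vector("list", length(targets))
    for (i in seq_along(targets)) {
      tg <- targets[[i]]
      m <- tg$mult %||% up
      if (direction < 0) m <- 2 - m   # same magnitude, opposite direction
      lab <- sprintf("%s_%s_x%.2g", if (direction > 0) "train" else "valid",
                     tg$id, m)
      out[[i]] <- if (tg$type == "enzyme") {
        mk(lab, enzymes = stats::setNames(m, tg$id))
      } else {
        mk(lab, boundary = stats::setNames(m, tg$id))
      }
    }
    out
  }
  list(training = build(+1), validation = build(-1))
}

#' Generate the bundled perturbation datasets from the true model
#'
#' Applies every training and validation perturbation to the true model,
#' records the steady-state fluxes of the nine cycle reactions, and builds
#' 10% and 20% multiplicative-noise variants of the training observations.
#' Non-convergence of any fixture perturbation is a hard error. Bit-identical
#' for a fixed seed.
#'
#' @param seed integer seed for the noise variants.
#' @return list with `training`, `validation` (lists of
#'   `list(pert, v_obs, weights)`), `training_noise10`, `training_noise20`,
#'   and `reference` (the reference steady state).
#' @export
generate_datasets <- function(seed = 1L) {
  true <- build_true_model()
  perts <- methionine_perturbations()
  run <- function(plist) {
    lapply(plist, function(pt) {
      ss <- solve_steady_state(true, pt)
      if (!ss$converged) {
        stop("fixture perturbation '", pt$label, "' did not converge")
      }
      list(pert = pt, v_obs = ss$v, weights = abs(ss$v))
    })
  }
  training <- run(perts$training)
  validation <- run(perts$validation)
  noisify <- function(datasets, sd_rel, seed_off) {
    lapply(seq_along(datasets), function(i) {
      d <- datasets[[i]]
      d$v_obs <- add_observation_noise(d$v_obs, sd_rel,
                                       seed = seed + seed_off + i)
      d$weights <- abs(d$v_obs)
      d
    })
  }
  list(training = training, validation = validation,
       training_noise10 = noisify(training, 0.10, 1000L),
       training_noise20 = noisify(training, 0.20, 2000L),
       reference = solve_steady_state(true))
}
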