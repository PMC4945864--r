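test_that("sampled reversibilities allocate the full driving force per route", {
  m3 <- mech_ordered("uni", bind = list("S"), release = list("P"))
  RT <- 2.5787
  set.seed(1)
  aux <- sample_auxiliary(m3, dG_r = -10, RT = RT)
  expect_equal(prod(aux$reversibilities), exp(-10 / RT), tolerance = 1e-12)
  expect_equal(sum(aux$abundances), 1, tolerance = 1e-12)
  expect_true(all(aux$reversibilities > 0 & aux$reversibilities < 1))

  # a minimal two-step cycle still allocates the whole driving force
  m1 <- reaction_mechanism("one", c("E", "ES"),
                           list(mech_step("E", "ES", bind = "S"),
                                mech_step("ES", "E", release = "P",
                                          catalytic = TRUE)),
                           routes = list(1:2))
  set.seed(2)
  aux1 <- sample_auxiliary(m1, dG_r = -5, RT = RT)
  expect_equal(prod(aux1$reversibilities), exp(-5 / RT), tolerance = 1e-12)

  # degenerate driving forces are rejected
  expect_error(sample_auxiliary(m3, dG_r = 0), "driving force")
  expect_error(sample_auxiliary(m3, dG_r = +3), "negative")

  # seed determinism
  set.seed(33); a1 <- sample_auxiliary(m3, -10)
  set.seed(33); a2 <- sample_auxiliary(m3, -10)
  expect_identical(a1, a2)
  set.seed(34); a3 <- sample_auxiliary(m3, -10)
  expect_false(identical(a1$reversibilities, a3$reversibilities))
})

test_that("elementary normalization reproduces the stated one-way fluxes", {
  # uni-uni, v_ref = 1, all reversibilities 1/2, equal abundances 1/3:
  # every forward one-way flux = 2, reverse = 1, forward constants = 6
  m3 <- mech_ordered("uni", bind = list("S"), release = list("P"))
  aux <- list(abundances = stats::setNames(rep(1 / 3, 3), m3$states),
              reversibilities = rep(0.5, 3),
              branch_fractions = 1, allosteric = NULL)
  kc <- assemble_rate_constants(m3, aux, v_ref_mag = 1)
  expect_equal(unname(kc$kf), rep(6, 3))
  expect_equal(unname(kc$kr), rep(3, 3))

  # irreversible limit: reverse constants vanish, forward one-way -> v_route
  aux0 <- aux; aux0$reversibilities <- rep(1e-12, 3)
  kc0 <- assemble_rate_constants(m3, aux0, 1)
  expect_equal(unname(kc0$kr), rep(0, 3), tolerance = 1e-9)
  expect_equal(unname(kc0$kf), rep(3, 3), tolerance = 1e-9)

  expect_error(assemble_rate_constants(
    m3, within(aux, reversibilities[2] <- 1.2), 1), "reversibility")
})

test_that("branched mechanisms split flux by the branching fractions", {
  mr <- mech_random_bi("rnd", "A", "B", release = "C")
  set.seed(5)
  aux <- sample_auxiliary(mr, dG_r = -12)
  aux$branch_fractions <- c(0.7, 0.3)
  kc <- assemble_rate_constants(mr, aux, v_ref_mag = 1)
  # at reference (x = 1, sampled abundances) the step one-way net fluxes are
  # 0.7/0.3 on the exclusive segments and 1.0 on the shared segment
  a <- aux$abundances
  from <- vapply(mr$steps, `[[`, character(1), "from")
  to <- vapply(mr$steps, `[[`, character(1), "to")
  net_step <- kc$kf * a[from] - kc$kr * a[to]
  expect_equal(unname(net_step[1:2]), c(0.7, 0.7), tolerance = 1e-12)
  expect_equal(unname(net_step[3:4]), c(0.3, 0.3), tolerance = 1e-12)
  expect_equal(unname(net_step[5:6]), c(1, 1), tolerance = 1e-12)
  # both routes satisfy the full thermodynamic constraint
  for (rt in mr$routes) {
    expect_equal(prod(aux$reversibilities[rt]), exp(-12 / 2.5787),
                 tolerance = 1e-9)
  }
})

test_that("MWC constants are recovered from the reference auxiliary draws", {
  # rho = 0.5 with a unit saturation term (no effectors) -> L = 1
  m0 <- mech_ordered("reg0", bind = list("S"), release = list("P"),
                     allosteric = list(n = 1, activators = character(),
                                       inhibitors = character()))
  al0 <- assemble_allosteric(
    m0, list(allosteric = list(rho = 0.5, saturations = numeric())))
  expect_equal(al0$L, 1)

  # one inhibitor at half saturation: K_eff = 1 and the T-state occupancy
  # halves L relative to the bare transition
  m <- mech_ordered("reg", bind = list("S"), release = list("P"),
                    allosteric = list(n = 1, activators = character(),
                                      inhibitors = "I"))
  aux <- list(allosteric = list(rho = 0.5, saturations = c(I = 0.5)))
  al <- assemble_allosteric(m, aux)
  expect_equal(unname(al$K_inh), 1)
  expect_equal(al$L, 0.5)

  # tetramer round trip: re-evaluating the regulatory state at reference
  # recovers the sampled R fraction
  m4 <- mech_ordered("reg4", bind = list("S"), release = list("P"),
                     allosteric = list(n = 4, activators = character(),
                                       inhibitors = "I"))
  aux4 <- list(allosteric = list(rho = 0.2, saturations = c(I = 0.3)))
  al4 <- assemble_allosteric(m4, aux4)
  ti_ref <- unname(1 + 1 / al4$K_inh)
  Q_ref <- al4$L * (ti_ref / 1)^4
  expect_equal(1 / (1 + Q_ref), 0.2, tolerance = 1e-12)
  expect_equal(al4$L, (1 - 0.2) / 0.2 * (1 / ti_ref)^4)

  expect_error(assemble_allosteric(
    m4, list(allosteric = list(rho = 0.2, saturations = c(I = 1)))),
    "degenerate")
})

test_that("anchoring and thermodynamic sign hold for every prior particle", {
  fx <- met_fixture()
  plan <- rate_plan(fx$net, fx$ref)
  xf <- ref_x(fx$net)
  worst <- 0
  for (i in 1:200) {
    pt <- sample_prior_particle(fx$net, fx$ref, seed = 7000 + i, plan = plan)
    v <- network_fluxes(plan, pt, xf)
    worst <- max(worst, max(abs(v - fx$ref$v_ref) / abs(fx$ref$v_ref)))
  }
  expect_lt(worst, 1e-9)

  # thermodynamic sign at random strictly positive compositions: flux opposes
  # the concentration-adjusted Gibbs energy for every reaction
  set.seed(99)
  pt <- sample_prior_particle(fx$net, fx$ref, seed = 1)
  Sb <- fx$net$S[fx$net$balanced, ]
  for (k in 1:25) {
    x <- xf
    x[rownames(Sb)] <- exp(stats::runif(6, -1.5, 1.5))
    v <- network_fluxes(plan, pt, x)
    dG_x <- fx$ref$dG_r + fx$ref$RT * drop(crossprod(Sb, log(x[rownames(Sb)])))
    expect_true(all(sign(v) == -sign(dG_x) | abs(v) < 1e-12))
  }
})

test_that("Haldane identity: zero flux at the implied equilibrium composition", {
  fx <- met_fixture()
  pt <- sample_prior_particle(fx$net, fx$ref, seed = 21)
  RT <- fx$ref$RT
  xf <- ref_x(fx$net)
  # uni-uni reversible example: move AdoHcy/Hcy to the AHC equilibrium ratio
  keq <- exp(-fx$ref$dG_r[["AHC"]] / RT)   # normalized-unit Keq incl. Ade
  x <- xf; x["Hcy"] <- 3; x["Ade"] <- 1; x["AdoHcy"] <- 3 / keq
  expect_lt(abs(rate_law(fx$net, fx$ref, pt, "AHC", x = x)), 1e-9)
  # bi-bi example (MS): scale product concentrations onto the equilibrium
  keq_ms <- exp(-fx$ref$dG_r[["MS"]] / RT)
  x2 <- xf; x2["Hcy"] <- 0.8; x2["MTHF"] <- 1.2
  x2["Met"] <- 2; x2["CH2THF"] <- keq_ms * 0.8 * 1.2 / 2
  expect_lt(abs(rate_law(fx$net, fx$ref, pt, "MS", x = x2)), 1e-9)
})

test_that("QSSA evaluation equals King-Altman spanning-tree enumeration", {
  # ordered uni-uni over a 10-point concentration grid
  toy <- toy_chain()
  pt <- sample_prior_particle(toy$net, toy$ref, seed = 3)
  plan <- rate_plan(toy$net, toy$ref)
  mech <- toy$net$mechanisms$R1
  for (s in seq(0.2, 2, length.out = 10)) {
    x <- c(A = s, P = 0.7)
    v_qssa <- rate_law(toy$net, toy$ref, pt, "R1", x = x)
    v_ka <- king_altman_flux(mech, pt$reactions$R1$kf, pt$reactions$R1$kr, x)
    expect_equal(v_qssa, v_ka, tolerance = 1e-9)
  }
  # random-order bi-bi (branched: generic linear-system path)
  rb <- toy_random_bi()
  ptb <- sample_prior_particle(rb$net, rb$ref, seed = 9)
  mb <- rb$net$mechanisms$R1
  set.seed(11)
  for (k in 1:10) {
    x <- stats::setNames(exp(stats::runif(3, -1, 1)), c("A", "B", "C"))
    v_qssa <- rate_law(rb$net, rb$ref, ptb, "R1", x = x)
    v_ka <- king_altman_flux(mb, ptb$reactions$R1$kf, ptb$reactions$R1$kr, x)
    expect_equal(v_qssa, v_ka, tolerance = 1e-9)
  }
})

test_that("uni-uni canonical parameters reproduce the Michaelis-Menten curve", {
  toy <- toy_chain()
  pt <- sample_prior_particle(toy$net, toy$ref, seed = 17)
  cn <- canonical_uni_uni(pt$reactions$R1$kf, pt$reactions$R1$kr)
  for (s in c(0.05, 0.3, 1, 4)) {
    v <- rate_law(toy$net, toy$ref, pt, "R1", x = c(A = s, P = 1e-12))
    expect_equal(v, cn[["kcat_f"]] * s / (cn[["Km_S"]] + s), tolerance = 1e-6)
  }
})

test_that("methionine particles have 72 parameters and serialize losslessly", {
  fx <- met_fixture()
  pt1 <- sample_prior_particle(fx$net, fx$ref, seed = 1)
  pp <- particle_params(pt1)
  expect_length(pp, 72L)

  # same seed -> bit-identical; different seed -> different
  pt1b <- sample_prior_particle(fx$net, fx$ref, seed = 1)
  expect_identical(particle_params(pt1b), pp)
  pt2 <- sample_prior_particle(fx$net, fx$ref, seed = 2)
  expect_false(identical(particle_params(pt2), pp))

  # write -> read -> rebuild gives the same fluxes everywhere
  tf <- tempfile(fileext = ".tsv")
  write_particles(list(pt1, pt2), tf)
  tab <- read_particle_params(tf)
  expect_equal(nrow(tab), 2L)
  back <- particle_from_params(fx$net, unlist(tab[1, -1, drop = FALSE]))
  plan <- rate_plan(fx$net, fx$ref)
  set.seed(5)
  x <- ref_x(fx$net); x[1:6] <- exp(stats::runif(6, -1, 1))
  expect_equal(network_fluxes(plan, back, x), network_fluxes(plan, pt1, x),
               tolerance = 1e-9)
})
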