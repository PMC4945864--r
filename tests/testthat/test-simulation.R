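test_that("identity perturbation is a fixed point for anchored particles", {
  fx <- met_fixture()
  pt <- sample_prior_particle(fx$net, fx$ref, seed = 77)
  model <- ensemble_model(fx$net, fx$ref, pt)
  ss <- solve_steady_state(model)
  expect_true(ss$converged)
  expect_equal(unname(ss$x), rep(1, 6), tolerance = 1e-9)
  expect_equal(ss$v, fx$ref$v_ref, tolerance = 1e-9)
})

test_that("the linear toy matches its closed-form steady state", {
  # irreversible Michaelis-Menten drain: e g(A) = b solves to
  # A* = Km b / (Vf - b)
  toy <- toy_chain(b = 1)
  pt <- sample_prior_particle(toy$net, toy$ref, seed = 5)
  # overwrite with a hand-built irreversible particle: kr = (km1, 0, 0)
  pt$reactions$R1$kf <- c(4, 3, 5)
  pt$reactions$R1$kr <- c(2, 0, 0)
  pt$reactions$R1$aux <- NULL
  cn <- canonical_uni_uni(pt$reactions$R1$kf, pt$reactions$R1$kr)
  A_star <- cn[["Km_S"]] * 1 / (cn[["kcat_f"]] - 1)
  model <- ensemble_model(toy$net, toy$ref, pt)
  ss <- solve_steady_state(model)
  expect_true(ss$converged)
  expect_equal(unname(ss$x["A"]), unname(A_star), tolerance = 1e-8)
  expect_equal(unname(ss$v["R1"]), 1, tolerance = 1e-8)
})

test_that("solutions are independent of the starting point (monostable toy)", {
  toy <- toy_branched()
  pt <- sample_prior_particle(toy$net, toy$ref, seed = 8)
  model <- ensemble_model(toy$net, toy$ref, pt)
  p <- perturbation("up", boundary = c(IN = 1.2))
  s1 <- solve_steady_state(model, p, x0 = c(A = 0.05))
  s2 <- solve_steady_state(model, p, x0 = c(A = 12))
  expect_true(s1$converged && s2$converged)
  expect_equal(s1$x, s2$x, tolerance = 1e-6)
})

test_that("moiety totals are conserved in perturbed methionine solves", {
  fx <- met_fixture()
  w <- fx$ref$x_ref[c("MTHF", "CH2THF")]
  total0 <- sum(w * 1)
  for (seed in c(3, 9)) {
    pt <- sample_prior_particle(fx$net, fx$ref, seed = seed)
    model <- ensemble_model(fx$net, fx$ref, pt)
    for (pp in list(perturbation("e", enzymes = c(MTHFR = 1.4)),
                    perturbation("b", boundary = c(INFLUX = 1.2)))) {
      ss <- solve_steady_state(model, pp)
      if (!ss$converged) next
      total <- sum(w * ss$x[c("MTHF", "CH2THF")])
      expect_equal(total, total0, tolerance = 1e-8)
      expect_true(all(ss$x > 0))
      # flux balance at the solution
      resid <- kinabc:::S_balanced(fx$net) %*% ss$v +
        fx$net$S_boundary[fx$net$balanced, ] %*% ss$v_boundary
      expect_lt(max(abs(resid)), 1e-8 * max(abs(fx$ref$v_ref)))
    }
  }
})

test_that("Jacobian stability matches the analytic 1-D rate of decay", {
  # dx/dt = b - e k x has the single eigenvalue -e k
  mets <- c("A", "P")
  S <- matrix(c(-1, 1), 2, 1, dimnames = list(mets, "R1"))
  net <- metabolic_network(mets, S, "R1", balanced = c(TRUE, FALSE),
                           boundary = list(IN = list(stoich = c(A = 1),
                                                     v_ref = 1)))
  k <- 2.5
  flux_fun <- function(x_bal, e_mult, b_mult, b_add) {
    list(v = c(R1 = k * unname(x_bal["A"]) * unname(e_mult["R1"])),
         vb = c(IN = unname(b_mult["IN"]) * 1))
  }
  ref <- reference_state(v_ref = c(R1 = 1), dG_r = c(R1 = -10),
                         boundary_ref = c(IN = 1), x_ref = c(A = 1 / k))
  model <- kinetic_model(net, ref, flux_fun,
                         conc_scale = c(A = 1), x0 = c(A = 1 / k))
  ss <- solve_steady_state(model)
  expect_true(ss$converged)
  js <- jacobian_stability(model, ss)
  expect_true(js$stable)
  expect_equal(js$leading_real_part, -k, tolerance = 1e-6)
})

test_that("the compiled solver agrees with the pure-R solver", {
  fx <- met_fixture()
  p2 <- perturbation("influx_up", boundary = c(INFLUX = 1.5))
  for (seed in c(2, 13)) {
    pt <- sample_prior_particle(fx$net, fx$ref, seed = seed)
    mc <- ensemble_model(fx$net, fx$ref, pt)
    mr <- mc; mr$cpp <- NULL
    sc <- solve_steady_state(mc, p2, fallback = FALSE)
    sr <- solve_steady_state(mr, p2, fallback = FALSE)
    expect_equal(sc$converged, sr$converged)
    if (sc$converged) {
      expect_equal(sc$x, sr$x, tolerance = 1e-6)
      expect_equal(sc$v, sr$v, tolerance = 1e-6)
    }
  }
})

test_that("non-convergence is reported as an outcome, not an error", {
  # drain capacity below the boundary influx: no steady state exists
  toy <- toy_chain(b = 1)
  pt <- sample_prior_particle(toy$net, toy$ref, seed = 5)
  pt$reactions$R1$kf <- c(4, 0.2, 0.2)   # kcat-limited far below b
  pt$reactions$R1$kr <- c(2, 0, 0)
  model <- ensemble_model(toy$net, toy$ref, pt)
  ss <- solve_steady_state(model, perturbation("up", boundary = c(IN = 10)))
  expect_false(ss$converged)
  expect_s3_class(ss, "steady_state")
})
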