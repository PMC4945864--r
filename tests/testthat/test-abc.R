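test_that("the weighted infinity-norm distance behaves as specified", {
  v <- c(a = 1, b = -2, c = 0.5)
  expect_equal(flux_distance(v, v, abs(v)), 0)
  # uniform 20% inflation with |v_exp| weights sits exactly on the boundary
  expect_equal(flux_distance(1.2 * v, v, abs(v)), 0.2, tolerance = 1e-12)
  # symmetry and brute-force oracle on random vectors
  set.seed(3)
  for (k in 1:10) {
    x <- stats::rnorm(9); y <- stats::rnorm(9); w <- stats::runif(9, 0.5, 2)
    manual <- 0
    for (i in 1:9) manual <- max(manual, abs(x[i] - y[i]) / w[i])
    expect_equal(flux_distance(x, y, w), manual, tolerance = 1e-15)
    expect_equal(flux_distance(x, y, w), flux_distance(y, x, w))
  }
  expect_error(flux_distance(v, v, c(1, 0, 1)), "positive")
  expect_error(flux_distance(v, v[1:2], c(1, 1)), "length")
})

test_that("an empty dataset list returns pure prior draws", {
  toy <- toy_branched()
  ps <- rejection_sample(toy$net, toy$ref, list(),
                         abc_config(n_particles = 25L, rng_seed = 3L))
  expect_equal(ps$acceptance_rate, 1)
  expect_length(ps$particles, 25L)
})

test_that("acceptance is monotone in the dataset count and eps -> Inf recovers the prior", {
  toy <- toy_branched()
  td <- toy_datasets(toy, true_seed = 41L)
  cfg <- function(eps) abc_config(epsilon_T = eps, n_particles = 400L,
                                  rng_seed = 5L, max_proposals = 400L)
  # scan the same 400 proposals under nested dataset collections
  rates <- vapply(0:4, function(k) {
    rejection_sample(toy$net, toy$ref, td$datasets[seq_len(k)],
                     cfg(0.2))$acceptance_rate
  }, numeric(1))
  expect_true(all(diff(rates) <= 1e-12))
  expect_equal(rates[1], 1)

  # with an effectively infinite tolerance the posterior equals the prior
  # draw-for-draw (same proposal seed stream)
  prior <- rejection_sample(toy$net, toy$ref, list(), cfg(0.2))
  wide <- rejection_sample(toy$net, toy$ref,
                           list(list(pert = perturbation("id"),
                                     v_obs = td$datasets[[1]]$v_obs)),
                           cfg(1e9))
  expect_equal(length(wide$particles), length(prior$particles))
  expect_identical(particle_params(wide$particles[[7]]),
                   particle_params(prior$particles[[7]]))
})

test_that("posterior expectancy reduces to exact means and intervals", {
  toy <- toy_branched()
  ps <- rejection_sample(toy$net, toy$ref, list(),
                         abc_config(n_particles = 40L, rng_seed = 9L))
  cons <- posterior_expectancy(ps, function(p) c(one = 1))
  expect_equal(unname(cons$mean), 1)
  expect_equal(unname(cons$upper - cons$lower), 0)

  ex <- posterior_expectancy(ps, particle_params)
  M <- do.call(rbind, lapply(ps$particles, particle_params))
  expect_equal(ex$mean, colMeans(M), tolerance = 1e-12)
  # functional failures are skipped and counted
  flaky <- local({
    i <- 0L
    function(p) { i <<- i + 1L; if (i %% 5L == 0L) stop("boom"); c(z = 1) }
  })
  fl <- posterior_expectancy(ps, flaky)
  expect_equal(fl$n_skipped, 8L)
  expect_equal(fl$n_used, 32L)
})

test_that("convergence metrics match a direct computation", {
  toy <- toy_branched()
  prior <- rejection_sample(toy$net, toy$ref, list(),
                            abc_config(n_particles = 30L, rng_seed = 2L))
  sub <- prior
  sub$particles <- prior$particles[1:10]
  out <- convergence_metrics(prior, list(prior, sub))
  # posterior = prior: distance 0, ratio 1
  expect_equal(out$expectancy_distance[1], 0, tolerance = 1e-12)
  expect_equal(out$variance_ratio[1], 1, tolerance = 1e-12)
  # independent hand computation for the subset
  P0 <- do.call(rbind, lapply(prior$particles, particle_params))
  P1 <- P0[1:10, ]
  d_hand <- sqrt(sum((colMeans(P1) - colMeans(P0))^2)) /
    sqrt(sum(colMeans(P0)^2))
  r_hand <- sqrt(sum(apply(P1, 2, sd)^2)) / sqrt(sum(apply(P0, 2, sd)^2))
  expect_equal(out$expectancy_distance[2], d_hand, tolerance = 1e-12)
  expect_equal(out$variance_ratio[2], r_hand, tolerance = 1e-12)
})

test_that("predictive distributions collapse on v_ref for the identity case", {
  toy <- toy_branched()
  ps <- rejection_sample(toy$net, toy$ref, list(),
                         abc_config(n_particles = 20L, rng_seed = 4L))
  pred <- predict_perturbations(ps, list(perturbation("id")))
  sm <- pred$summaries[[1]]
  expect_equal(sm$median, unname(toy$ref$v_ref[sm$reaction]), tolerance = 1e-8)
  expect_equal(sm$q2.5, sm$q97.5, tolerance = 1e-8)

  # RMSFE algebra: predictions offset by +0.1 on every reaction give 0.1
  truth_shift <- list(toy$ref$v_ref - 0.1)
  pred2 <- predict_perturbations(ps, list(perturbation("id")),
                                 truth = truth_shift)
  expect_equal(unname(pred2$rmsfe[, 1]), rep(0.1, 20L), tolerance = 1e-8)
})

test_that("hypersphere perturbations have exact norm and sphere marginals", {
  rxns <- paste0("R", 1:9)
  ps <- random_enzyme_perturbations(0, 3, rxns, seed = 1)
  for (p in ps) expect_equal(unname(p$enzymes), rep(1, 9))

  ps1 <- random_enzyme_perturbations(0.4, 50, rxns, seed = 2)
  for (p in ps1) {
    expect_equal(sqrt(sum(attr(p, "deltaE")^2)), 0.4, tolerance = 1e-12)
  }
  # first coordinate of a uniform direction on S^8: (u+1)/2 ~ Beta(4, 4)
  ps2 <- random_enzyme_perturbations(1, 4000, rxns, seed = 3)
  u <- vapply(ps2, function(p) attr(p, "deltaE")[[1]], numeric(1))
  ks <- stats::ks.test((u + 1) / 2, stats::pbeta, 4, 4)
  expect_gt(ks$p.value, 0.01)
})

test_that("observation noise has the stated relative spread", {
  expect_identical(add_observation_noise(c(a = 1), 0), c(a = 1))
  x <- rep(2, 1e5)
  y <- add_observation_noise(x, 0.1, seed = 8)
  expect_equal(sd(y) / mean(y), 0.1, tolerance = 0.01)
  # near-zero fluxes may flip sign; the count is reported
  z <- add_observation_noise(stats::setNames(rep(1e-3, 100), NULL), 2, seed = 9)
  expect_gt(attr(z, "sign_flips"), 0)
})

test_that("parameter recovery: true canonical constants sit in the 95% intervals", {
  toy <- toy_branched()
  td <- toy_datasets(toy, true_seed = 41L)
  truth <- unlist(lapply(c("R1", "R2"), function(rx) {
    stats::setNames(canonical_uni_uni(td$true_particle$reactions[[rx]]$kf,
                                      td$true_particle$reactions[[rx]]$kr),
                    paste0(rx, ".", c("kcat_f", "Km_S", "kcat_r", "Km_P")))
  }))
  canon_fun <- function(p) {
    unlist(lapply(c("R1", "R2"), function(rx) {
      canonical_uni_uni(p$reactions[[rx]]$kf, p$reactions[[rx]]$kr)
    }))
  }
  hits <- 0L; total <- 0L
  for (rep_i in 1:20) {
    ps <- rejection_sample(toy$net, toy$ref, td$datasets,
                           abc_config(n_particles = 40L,
                                      rng_seed = 100L + rep_i,
                                      max_proposals = 20000L))
    ex <- posterior_expectancy(ps, canon_fun)
    hits <- hits + sum(truth >= ex$lower & truth <= ex$upper)
    total <- total + length(truth)
  }
  expect_gte(hits / total, 0.9)
})
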