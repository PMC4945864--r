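test_that("pinned concentrations give the closed-form Gibbs energy", {
  mets <- c("A", "B")
  S <- matrix(c(-1, 1), 2, 1, dimnames = list(mets, "R1"))
  net <- metabolic_network(mets, S, "R1",
                           mechanisms = list(R1 = mech_ordered(
                             "R1", bind = list("A"), release = list("B"))))
  xa <- log(2e-4); xb <- log(5e-5)
  th <- thermo_input(dG0_r = c(R1 = -7),
                     ln_x_min = c(A = xa, B = xb), ln_x_max = c(A = xa, B = xb),
                     v_ref_signs = c(R1 = 1))
  r <- gibbs_ranges(net, th)
  expected <- -7 + th$RT * (xb - xa)
  expect_equal(r$dG_min, expected, tolerance = 1e-9)
  expect_equal(r$dG_max, expected, tolerance = 1e-9)
  expect_equal(reference_dG(r)[["R1"]], expected, tolerance = 1e-9)
})

test_that("LP ranges match a brute-force grid search on a small network", {
  mets <- c("A", "B", "C")
  S <- matrix(c(-1, 1, 0,
                0, -1, 1), 3, 2, dimnames = list(mets, c("R1", "R2")))
  net <- metabolic_network(mets, S, c("R1", "R2"))
  lo <- c(A = log(1e-5), B = log(2e-5), C = log(5e-6))
  hi <- c(A = log(2e-3), B = log(1e-3), C = log(4e-4))
  th <- thermo_input(dG0_r = c(R1 = -6, R2 = -4), ln_x_min = lo,
                     ln_x_max = hi, v_ref_signs = c(R1 = 1, R2 = 1))
  r <- gibbs_ranges(net, th)
  # oracle: exhaustive 50^3 lattice respecting the direction constraints of
  # the *other* reaction (mirrors the range definition)
  grid <- lapply(seq_along(mets), function(i) seq(lo[i], hi[i], length.out = 50))
  G <- as.matrix(expand.grid(grid))
  dg <- cbind(-6 + th$RT * (G %*% S[, 1]), -4 + th$RT * (G %*% S[, 2]))
  res <- 3 * max((hi - lo) / 49) * th$RT   # grid resolution in kJ/mol
  for (j in 1:2) {
    other_ok <- dg[, -j] < 0
    expect_lt(abs(r$dG_min[j] - min(dg[dg[, j] < 0 & other_ok, j])), res)
    expect_lt(abs(r$dG_max[j] - max(dg[other_ok, j])), res)
  }
})

test_that("methionine screening: 4 of 9 reactions strictly irreversible", {
  fx <- met_fixture()
  r <- fx$ranges
  irr <- r$reaction[r$reversibility_label == "strictly_irreversible"]
  expect_setequal(irr, c("MATI", "MATIII", "GNMT", "MTHFR"))
  # the transsulfuration branch and methionine synthase run near equilibrium
  neq <- r$reaction[r$reversibility_label == "near_equilibrium"]
  expect_setequal(neq, c("CBS", "MS"))
  # the strongest driving force sits on the initial MAT steps
  expect_setequal(r$reaction[rank(r$midpoint) <= 2], c("MATI", "MATIII"))
})

test_that("ranges are permutation invariant and monotone in the bounds", {
  net <- methionine_network()
  th <- methionine_thermo()
  r0 <- gibbs_ranges(net, th)
  # permute metabolite rows and reaction columns
  set.seed(7)
  pm <- sample(length(net$metabolites)); pr <- sample(length(net$reactions))
  net2 <- metabolic_network(net$metabolites[pm],
                            net$S[pm, pr, drop = FALSE],
                            net$reactions[pr],
                            balanced = net$balanced[pm],
                            boundary = net$boundary, pools = net$pools)
  r2 <- gibbs_ranges(net2, th)
  ord <- match(r0$reaction, r2$reaction)
  expect_equal(r2$dG_min[ord], r0$dG_min, tolerance = 1e-8)
  expect_equal(r2$dG_max[ord], r0$dG_max, tolerance = 1e-8)

  # tightening any bound never widens any range
  th_tight <- th
  th_tight$ln_x_max <- th$ln_x_max - 0.5
  th_tight$ln_x_min <- th$ln_x_min + 0.5
  rt <- gibbs_ranges(net, th_tight)
  expect_true(all(rt$dG_min >= r0$dG_min - 1e-9))
  expect_true(all(rt$dG_max <= r0$dG_max + 1e-9))

  # direction constraint: every midpoint opposes the reference flux direction
  expect_true(all(sign(r0$midpoint) == -1))
})

test_that("the sampling hook draws uniformly within each range", {
  fx <- met_fixture()
  d1 <- reference_dG(fx$ranges, sample = TRUE, seed = 4)
  d2 <- reference_dG(fx$ranges, sample = TRUE, seed = 4)
  expect_identical(d1, d2)
  expect_true(all(d1 >= fx$ranges$dG_min & d1 <= fx$ranges$dG_max))
  # Monte-Carlo mean of repeated draws approaches the midpoint
  r1 <- fx$ranges[1, ]
  draws <- replicate(2000, reference_dG(fx$ranges[1, , drop = FALSE],
                                        sample = TRUE))
  se <- (r1$dG_max - r1$dG_min) / sqrt(12 * 2000)
  expect_lt(abs(mean(draws) - r1$midpoint), 4 * se)
})

test_that("tabular thermodynamic input reproduces the programmatic fixture", {
  th0 <- methionine_thermo()
  th1 <- read_thermo_tables(
    system.file("extdata", "methionine_thermo_reactions.tsv", package = "kinabc"),
    system.file("extdata", "methionine_thermo_metabolites.tsv", package = "kinabc"),
    v_ref_signs = th0$v_ref_signs)
  expect_equal(th1$dG0_r[names(th0$dG0_r)], th0$dG0_r, tolerance = 1e-3)
  expect_equal(th1$ln_x_min[names(th0$ln_x_min)], th0$ln_x_min, tolerance = 1e-4)
  r <- gibbs_ranges(methionine_network(), th1)
  expect_equal(sum(r$reversibility_label == "strictly_irreversible"), 4L)
})
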