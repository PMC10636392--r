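test_that("perturbations convert the advertised cell sets", {
  bh <- make_fixture("block_with_hole_10x10")$landscape
  # full-magnitude perimeter conversions are deterministic
  rm_all <- apply_perturbation(bh, perturbation_spec(
    "remove_perimeter_forest", 1), seed = 1)
  d <- grass_clusters(bh)
  border <- sum(interface_exposures(d, 1) > 0)
  expect_equal(sum(rm_all$cells == 1L) - sum(bh$cells == 1L), border)
  rm_all2 <- apply_perturbation(bh, perturbation_spec(
    "remove_perimeter_forest", 1), seed = 99)
  expect_identical(rm_all$cells, rm_all2$cells)
  add_all <- apply_perturbation(bh, perturbation_spec(
    "add_perimeter_forest", 1), seed = 1)
  expect_gt(state_fractions(add_all)[["F"]], state_fractions(bh)[["F"]])
  # vanishing magnitude still flips exactly one cell
  one <- apply_perturbation(bh, perturbation_spec(
    "remove_perimeter_forest", 1e-9), seed = 3)
  expect_equal(sum(one$cells != bh$cells), 1)
  # random mortality drops [F] by about the magnitude
  forest <- initial_landscape("all_forest", 30)
  m <- 0.2
  drops <- vapply(1:20, function(s) {
    pert <- apply_perturbation(forest, perturbation_spec(
      "random_mortality", m), seed = s)
    1 - state_fractions(pert)[["F"]]
  }, numeric(1))
  expect_equal(mean(drops), m, tolerance = 1e-6) # n fixed by rounding
  expect_error(apply_perturbation(forest, perturbation_spec(
    "random_recruitment", 0.5), seed = 1), "empty eligible")
  expect_error(perturbation_spec("random_mortality", 0), "magnitude")
})

test_that("sensitivity is the ratio of balance and cover changes", {
  p <- reference_params()
  bh <- make_fixture("block_with_hole_10x10")$landscape
  expect_error(sensitivity(bh, bh, p), "does not change")
  pert <- apply_perturbation(bh, perturbation_spec(
    "remove_perimeter_forest", 0.5), seed = 2)
  b0 <- net_rate(bh, p)
  b1 <- net_rate(pert, p)
  expect_equal(sensitivity(bh, pert, p),
               (b1$net - b0$net) / (b1$F - b0$F))
})

test_that("weighted-mean sensitivity reduces and scales correctly", {
  p <- reference_params()
  bh <- make_fixture("block_with_hole_10x10")$landscape
  # deterministic full-magnitude spec: every realisation identical, so the
  # ensemble mean equals the single-perturbation sensitivity
  spec <- perturbation_spec("remove_perimeter_forest", 1, weight = 0.4)
  pert <- apply_perturbation(bh, spec, seed = 1)
  lam1 <- sensitivity(bh, pert, p)
  expect_equal(as.numeric(mean_sensitivity(bh, list(spec), p,
                                           n_realizations = 3)), lam1)
  # identical perturbations with different weights: still the same value
  spec2 <- perturbation_spec("remove_perimeter_forest", 1, weight = 7)
  expect_equal(as.numeric(mean_sensitivity(bh, list(spec, spec2), p,
                                           n_realizations = 2)), lam1)
  # ratio form: rescaling all weights leaves the result unchanged
  specs <- default_perturbations(p, bh$N)
  a <- mean_sensitivity(bh, specs, p, n_realizations = 8, seed = 5)
  specs2 <- lapply(specs, function(s) {
    s$weight <- 2 * s$weight
    s
  })
  b <- mean_sensitivity(bh, specs2, p, n_realizations = 8, seed = 5)
  expect_equal(as.numeric(a), as.numeric(b))
})

test_that("sensitivity matches the mean-field derivative at low cover", {
  # uncorrelated low-cover landscapes follow the closed-form rate, so the
  # two-landscape sensitivity approximates its analytic F-derivative
  N <- 1e4
  p <- fgba_params(phiN = 0.5, N = N)
  pf <- spread_probabilities(p)[["pf"]]
  phiN <- p$phi * N
  an_deriv <- -p$beta + 4 * p$alpha * (1 - 2 * 0.06) - p$gamma -
    4 * phiN * pf * (1 - 4 * 0.06 + 3 * 0.06^2)
  lams <- vapply(1:20, function(s) {
    l1 <- initial_landscape("uniform_random", 100, 100, f = 0.05,
                            seed = 2 * s)
    l2 <- initial_landscape("uniform_random", 100, 100, f = 0.07,
                            seed = 2 * s + 1)
    sensitivity(l1, l2, p)
  }, numeric(1))
  expect_lt(abs(mean(lams) - an_deriv), 0.005)
})

test_that("a critical hole amplifies perimeter perturbations", {
  p <- fgba_params(beta = 0, gamma = 0, phiN = 0.5, N = 2500, check = FALSE)
  gc <- critical_hole_size(p, 2500)
  ls <- initial_landscape("forest_with_hole", 50, 50, hole_fraction = gc)
  for (kind in c("remove_perimeter_forest", "add_perimeter_forest")) {
    pert <- apply_perturbation(ls, perturbation_spec(kind, 1), seed = 1)
    expect_gt(sensitivity(ls, pert, p), 0)
  }
})

test_that("stable states dampen perturbations, the saddle amplifies", {
  N <- 2500
  p <- fgba_params(phiN = 1.32, N = N)
  # stabilise the saddle; evaluate each landscape at its own equilibrium phi
  cfg <- control_config(phiN0 = 1.32, gN = 100, N = N, F_ref = 0.7,
                        t0 = 150, T = 250)
  tr <- controlled_simulate(initial_landscape("forest_with_hole", 50, 50,
                                              hole_fraction = 0.3),
                            p, cfg, t_end = 410, seed = 13)
  est <- equilibrium_estimate(tr)
  saddle <- vegetation_view(tr$final)
  pe <- fgba_params(phiN = est[["phiN_bar"]], N = N)
  grass <- vegetation_view(simulate_fgba(
    initial_landscape("all_grass", 50, 50), p, 250, seed = 22)$final)
  forest <- vegetation_view(simulate_fgba(
    initial_landscape("all_forest", 50, 50), p, 250, seed = 21)$final)
  lam_saddle <- mean_sensitivity(saddle, default_perturbations(pe, N), pe,
                                 n_realizations = 32, seed = 3)
  lam_grass <- mean_sensitivity(grass, default_perturbations(p, N), p,
                                n_realizations = 32, seed = 4)
  lam_forest <- mean_sensitivity(forest, default_perturbations(p, N), p,
                                 n_realizations = 32, seed = 5)
  # both stable states dampen; the saddle sits above them (amplifying)
  expect_lt(lam_grass, 0)
  expect_lt(lam_forest, 0)
  expect_gt(lam_saddle, max(lam_grass, lam_forest))
  expect_gt(lam_saddle, -0.01)
  # the grassland state is the more resilient of the two
  expect_gt(abs(lam_grass), abs(lam_forest))
  # deep forest with small scattered mortality: clear dampening
  pm <- apply_perturbation(forest, perturbation_spec(
    "random_mortality", 0.05), seed = 9)
  expect_lt(sensitivity(forest, pm, p), 0)
})
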