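test_that("gain and loss terms evaluate the balance equation's sides", {
  p <- reference_params()
  expect_equal(gain_rate(1, 0, 0, p), -p$gamma)
  expect_equal(gain_rate(0, 1, 0, p), p$beta)
  # constructed root: alpha*FG = gamma*F - beta*G
  F <- 0.8333
  G <- 1 - F
  FG <- (p$gamma * F - p$beta * G) / p$alpha
  expect_equal(gain_rate(F, G, FG, p), 0)
  # single cluster, [G]=0.5, [FG]=0.1, phiN=1, pf=0.1 -> loss 5e-3
  m <- matrix(0L, 20, 20)
  m[, 1:10] <- 1L
  ls <- as_landscape(m)
  d <- grass_clusters(ls)
  expect_equal(d$nc, 1)
  expect_equal(sum(d$fg), 0.1)
  pe <- exact_ratio_params(phiN = 1, N = 400, check = FALSE)
  expect_equal(loss_rate(d, pe), 1 * 0.1 * 0.5 * 0.1)
  expect_equal(loss_rate(grass_clusters(initial_landscape("all_forest", 10)),
                         pe), 0)
})

test_that("the weighted-perimeter loss equals the per-cluster sum exactly", {
  # algebraic identity between the cluster sum and the [FG]cg form
  p <- exact_ratio_params(phiN = 0.7, N = 400, check = FALSE)
  pf <- spread_probabilities(p)[["pf"]]
  for (seed in 1:5) {
    ls <- random_landscape(20, seed = seed,
                           probs = c(F = 0.5, G = 0.5, B = 0, A = 0))
    d <- grass_clusters(ls)
    per_cluster <- sum(p$phi * d$N * d$g * pf * d$fg)
    expect_equal(loss_rate(d, p), per_cluster)
  }
})

test_that("net rate reduces to known values and respects the slow view", {
  p <- reference_params()
  b <- net_rate(initial_landscape("all_forest", 10), p)
  expect_equal(b$net, -p$gamma)
  expect_equal(b$gain - b$loss, b$net)
  # B/A cells count as grass in the slow view
  ls <- random_landscape(10, seed = 2)
  bs <- net_rate(ls, p)
  expect_equal(bs$G, 1 - state_fractions(ls)[["F"]])
  braw <- net_rate(ls, p, view = "raw")
  expect_equal(braw$G, state_fractions(ls)[["G"]])
})

test_that("balance predictions match finite differences along trajectories", {
  p <- reference_params(phiN = 0.257, N = 2500)
  xs <- c()
  ys <- c()
  for (s in 1:8) {
    ls <- initial_landscape("uniform_random", 50, 50, f = 0.3, seed = 400 + s)
    tr <- simulate_fgba(ls, p, t_end = 60, seed = 500 + s, record_dt = 0.5,
                        snapshot_times = seq(10, 50, by = 5))
    for (i in seq_along(tr$snapshots)) {
      tt <- tr$snapshot_times[i]
      xs <- c(xs, net_rate(tr$snapshots[[i]], p)$net)
      f1 <- tr$F[which.min(abs(tr$t - (tt - 5)))]
      f2 <- tr$F[which.min(abs(tr$t - (tt + 5)))]
      ys <- c(ys, (f2 - f1) / 10)
    }
  }
  slope <- unname(coef(stats::lm(ys ~ 0 + xs)))
  expect_gt(slope, 0.8)
  expect_lt(slope, 1.2)
})

test_that("single-cluster approximation holds at low forest cover", {
  p <- reference_params(phiN = 0.257, N = 2500)
  expect_equal(single_cluster_net_rate(0.4, 0, p, 2500),
               p$beta * 0.6 - p$gamma * 0.4)
  # constructed cancellation: alpha = phi pf N G
  p2 <- reference_params(phiN = 1.32, N = 2500)
  pf <- spread_probabilities(p2)[["pf"]]
  G <- p2$alpha / (p2$phi * pf * 2500)
  F <- 1 - G
  expect_equal(single_cluster_net_rate(F, 0.3, p2, 2500),
               p2$beta * G - p2$gamma * F)
  # agreement with the full balance on simulated low-cover landscapes
  ls <- initial_landscape("uniform_random", 50, 50, f = 0.08, seed = 31)
  tr <- simulate_fgba(ls, p, t_end = 40, seed = 32,
                      snapshot_times = c(20, 40))
  for (s in tr$snapshots) {
    v <- vegetation_view(s)
    if (state_fractions(v)[["F"]] > 0.2) next
    b <- net_rate(s, p)
    approx_net <- single_cluster_net_rate(b$F, b$FG, p, 2500)
    expect_lt(abs(approx_net - b$net), 0.25 * max(abs(b$gain), abs(b$loss)))
  }
})

test_that("emergent-curve fitting recovers a known smooth curve", {
  set.seed(99)
  true_fun <- function(F) 0.8 * F * (1 - F)^1.5
  F <- runif(400, 0.02, 0.95)
  noise_sd <- 0.01
  d <- data.frame(F = F,
                  FG = pmax(0, true_fun(F) + rnorm(400, 0, noise_sd)),
                  FGcg = pmax(0, true_fun(F) + rnorm(400, 0, noise_sd)))
  cv <- fit_emergent_curves(d)
  Fs <- seq(0.05, 0.9, by = 0.01)
  expect_lt(max(abs(cv$FG_star(Fs) - true_fun(Fs))), 2 * noise_sd)
  # degenerate equality scatter gives matching curves
  d2 <- d
  d2$FGcg <- d2$FG
  cv2 <- fit_emergent_curves(d2)
  expect_lt(max(abs(cv2$FG_star(Fs) - cv2$FGcg_star(Fs))), 1e-6)
  # anchored to zero at the pure states, never negative
  expect_lt(cv$FG_star(0), 1e-3)
  expect_lt(cv$FG_star(1), 1e-3)
  expect_true(all(cv$FG_star(seq(0, 1, 0.01)) >= 0))
  expect_true(all(cv$FGcg_star(Fs) <= cv$FG_star(Fs) + 1e-12))
  expect_error(fit_emergent_curves(d[1:10, ]), "50")
})

test_that("steady states of the emergent ODE are found with stability", {
  # engineered dynamics: phi = 0, FG* = c F (1-F) gives logistic-like roots
  # 0 and 1 - gamma/(alpha c)
  p <- fgba_params(beta = 0, gamma = 0.02, alpha = 0.03, phi = 0,
                   check = FALSE)
  cc <- 4
  set.seed(7)
  F <- runif(300, 0, 1)
  d <- data.frame(F = F, FG = cc * F * (1 - F), FGcg = cc * F * (1 - F))
  cv <- fit_emergent_curves(d, k = 30)
  ss <- ode_steady_states(cv, p, N = 2500)
  true_root <- 1 - p$gamma / (p$alpha * cc)
  expect_gte(nrow(ss), 1)
  expect_lt(min(abs(ss$F_star - true_root)), 1e-3)
  hit <- which.min(abs(ss$F_star - true_root))
  expect_true(ss$stable[hit])
  # with beta = 0 and anchored curves, bare ground is an equilibrium
  expect_lt(abs(p$beta * 1 - p$gamma * 0 + p$alpha * cv$FG_star(0)), 1e-5)
  # gradient structure: the potential -int(rhs) has a well at the stable root
  pf <- spread_probabilities(p)[["pf"]]
  rhs <- function(F) {
    p$beta * (1 - F) - p$gamma * F + p$alpha * cv$FG_star(F) -
      p$phi * pf * 2500 * (1 - F) * cv$FGcg_star(F)
  }
  Fs <- seq(cv$range[1], cv$range[2], length.out = 300)
  V <- -cumsum(rhs(Fs)) * diff(Fs)[1]
  well <- Fs[which.min(V)]
  expect_lt(abs(well - true_root), 0.02)
})

test_that("critical hole size follows from the no-demography balance", {
  p <- fgba_params(beta = 0, gamma = 0, phiN = 0.5, N = 2500, mu = 9e5,
                   rho_g = 8.1e6, rho_f = 1e5, check = FALSE)
  gc <- critical_hole_size(p, 2500)
  expect_equal(as.numeric(gc), 0.03 / (0.5 * 0.1))
  # complement identity with the unstable root of the hole dynamics
  Fc <- 1 - p$alpha / (0.5 * 0.1)
  expect_equal(as.numeric(gc) + Fc, 1)
  # phi1 form: [G]c = phi1 / phi
  expect_equal(as.numeric(gc), attr(gc, "phi1") / p$phi)
  # huge ignition rate: vanishing critical hole
  p2 <- fgba_params(beta = 0, gamma = 0, phiN = 1e6, N = 2500, check = FALSE)
  expect_lt(critical_hole_size(p2, 2500), 1e-4)
  expect_error(critical_hole_size(reference_params(), 2500), "gamma")
})
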