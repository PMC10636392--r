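#' Forest gain rate
#'
#' The gain side of the macroscopic balance of forest area:
#' `gain = beta [G] - gamma [F] + alpha [FG]` — spontaneous recruitment on
#' grass, spontaneous mortality, and forest spread along its perimeter.
#'
#' @param F,G cover fractions.
#' @param FG forest-grass pair density (N-normalised).
#' @param params an [fgba_params()] object.
#' @return Rate of change of `[F]` (1/y).
#' @export
gain_rate <- function(F, G, FG, params) {
  stopifnot(inherits(params, "fgba_params"))
  if (any(c(F, G, FG) < 0)) stop("F, G, FG must be non-negative")
  params$beta * G - params$gamma * F + params$alpha * FG
}

#' Forest loss rate from repeated fires
#'
#' The loss side of the balance: `loss = phi pf N [G] [FG]cg`, equal by
#' construction to the per-cluster sum `sum_j phi N [G]_j * pf [FG]_j`
#' (cluster-area-weighted ignition times expected single-fire loss).
#'
#' @param decomp an `fgba_clusters` decomposition.
#' @param params an [fgba_params()] object.
#' @param N cell count (defaults to the decomposition's lattice).
#' @return Rate of loss of `[F]` (1/y, non-negative).
#' @export
loss_rate <- function(decomp, params, N = decomp$N) {
  stopifnot(inherits(decomp, "fgba_clusters"),
            inherits(params, "fgba_params"))
  pf <- spread_probabilities(params)[["pf"]]
  G <- sum(decomp$g)
  params$phi * pf * N * G * weighted_forest_perimeter(decomp)
}

#' Net forest balance on a landscape
#'
#' Evaluates the balance equation
#' `d[F]/dt = beta [G] - gamma [F] + alpha [FG] - phi pf N [G] [FG]cg`
#' on the measured geometry of a landscape. By default the landscape is
#' first collapsed to its slow-timescale vegetation view (B and A mapped
#' to G; grass regrowth is much faster than forest dynamics, so a burnt
#' cell is effectively grass on the demographic timescale). Use
#' `view = "raw"` to evaluate on the instantaneous labels.
#'
#' @param landscape an `fgba_landscape`.
#' @param params an [fgba_params()] object.
#' @param view `"slow"` (default) or `"raw"`.
#' @return An `fgba_balance` object: list with `gain`, `loss`, `net`
#'   (`net = gain - loss` exactly) and the measured `F`, `G`, `FG`,
#'   `FGcg`.
#' @export
net_rate <- function(landscape, params, view = c("slow", "raw")) {
  stopifnot(inherits(landscape, "fgba_landscape"))
  view <- match.arg(view)
  if (view == "slow") landscape <- vegetation_view(landscape)
  fr <- state_fractions(landscape)
  FG <- pair_count(landscape, "F", "G")
  decomp <- grass_clusters(landscape)
  gain <- gain_rate(fr[["F"]], fr[["G"]], FG, params)
  loss <- loss_rate(decomp, params)
  structure(list(gain = gain, loss = loss, net = gain - loss,
                 F = fr[["F"]], G = fr[["G"]], FG = FG,
                 FGcg = weighted_forest_perimeter(decomp)),
            class = "fgba_balance")
}

#' @export
print.fgba_balance <- function(x, ...) {
  cat(sprintf("forest balance: gain %.4g - loss %.4g = net %.4g /y ([F]=%.3f)\n",
              x$gain, x$loss, x$net, x$F))
  invisible(x)
}

#' Single-cluster approximation of the balance equation
#'
#' When all grass belongs to one cluster, `[FG]cg = [FG]` and the balance
#' reduces to `d[F]/dt = beta G - gamma F + (alpha - phi pf N G) [FG]*`
#' with `G = 1 - F`. Valid for low forest cover (roughly `[F] < 0.2`),
#' where most grass belongs to the giant cluster.
#'
#' @param F forest cover fraction in `[0, 1]`.
#' @param FG_star_value the emergent steady-state perimeter `[FG]*(F)`.
#' @param params an [fgba_params()] object.
#' @param N cell count (converts per-cell `phi` to the domain rate).
#' @return Rate of change of `[F]` (1/y).
#' @export
single_cluster_net_rate <- function(F, FG_star_value, params, N) {
  stopifnot(inherits(params, "fgba_params"))
  if (any(F < 0 | F > 1)) stop("F must be in [0, 1]")
  pf <- spread_probabilities(params)[["pf"]]
  G <- 1 - F
  params$beta * G - params$gamma * F +
    (params$alpha - params$phi * pf * N * G) * FG_star_value
}

#' Fit the emergent perimeter curves
#'
#' Along simulated trajectories at fixed ignition rate, the perimeter
#' quantities `[FG]` and `[FG]cg` collapse onto narrow bands around
#' steady-state functions `[FG]*(F)` and `[FG]cg*(F)`: the fast geometry
#' is slaved to the slowly varying forest area. This fits those curves
#' nonparametrically (penalised thin-plate regression splines via
#' `mgcv::gam`, which also supplies pointwise standard errors).
#' Predictions are clamped to be non-negative, anchored to 0 at `F = 0`
#' and `F = 1` (no interface without both cover types), and
#' `[FG]cg*` is capped at `[FG]*` pointwise.
#'
#' @param data a data frame with columns `F`, `FG`, and `FGcg` (scatter
#'   samples, e.g. pooled from [run_ensemble()] runs with
#'   `record_pairs = TRUE`); at least 50 rows spanning an interval of `F`.
#' @param k spline basis dimension.
#' @return An `fgba_curves` object with elements `FG_star(F)` and
#'   `FGcg_star(F)` (vectorised functions returning fit, with attribute
#'   functions for standard errors via `se = TRUE`), `range` (supported
#'   F-interval), `residual_sd` per curve, and the input data.
#' @export
fit_emergent_curves <- function(data, k = 20) {
  need <- c("F", "FG", "FGcg")
  if (!all(need %in% names(data))) {
    stop("data must have columns F, FG, FGcg")
  }
  data <- data[stats::complete.cases(data[need]), need]
  if (nrow(data) < 50) stop("need at least 50 scatter points")
  rng <- range(data$F)
  if (diff(rng) < 0.05) stop("scatter must span an interval of F")
  k <- max(5, min(k, floor(nrow(data) / 5)))
  # zero anchors at the pure states, heavily weighted
  anchor <- data.frame(F = c(0, 1), y = c(0, 0))
  w_anchor <- nrow(data)
  fit_one <- function(y) {
    d <- data.frame(F = c(data$F, anchor$F), y = c(y, anchor$y))
    w <- c(rep(1, length(y)), rep(w_anchor, 2))
    mgcv::gam(y ~ s(F, k = k), data = d, weights = w)
  }
  m_fg <- fit_one(data$FG)
  m_cg <- fit_one(data$FGcg)
  pred <- function(model) {
    force(model)
    function(F, se = FALSE) {
      p <- mgcv::predict.gam(model, newdata = data.frame(F = F),
                             se.fit = se)
      if (se) {
        list(fit = pmax(0, as.numeric(p$fit)),
             se = as.numeric(p$se.fit))
      } else {
        pmax(0, as.numeric(p))
      }
    }
  }
  fg_fun <- pred(m_fg)
  cg_raw <- pred(m_cg)
  cg_fun <- function(F, se = FALSE) {
    if (se) {
      p <- cg_raw(F, se = TRUE)
      p$fit <- pmin(p$fit, fg_fun(F))
      p
    } else {
      pmin(cg_raw(F), fg_fun(F))
    }
  }
  structure(list(FG_star = fg_fun, FGcg_star = cg_fun, range = rng,
                 residual_sd = c(FG = stats::sd(data$FG - fg_fun(data$F)),
                                 FGcg = stats::sd(data$FGcg - cg_fun(data$F))),
                 data = data),
            class = "fgba_curves")
}

#' @export
print.fgba_curves <- function(x, ...) {
  cat(sprintf("emergent perimeter curves fitted on %d points, F in [%.3f, %.3f]\n",
              nrow(x$data), x$range[1], x$range[2]))
  cat(sprintf("  residual SD: FG %.4g, FGcg %.4g\n",
              x$residual_sd["FG"], x$residual_sd["FGcg"]))
  invisible(x)
}

#' @export
plot.fgba_curves <- function(x, ...) {
  Fs <- seq(x$range[1], x$range[2], length.out = 200)
  plot(x$data$F, x$data$FG, pch = 16, cex = 0.4, col = "#00000040",
       xlab = "[F]", ylab = "pair density", ...)
  graphics::points(x$data$F, x$data$FGcg, pch = 16, cex = 0.4,
                   col = "#d32f2f40")
  graphics::lines(Fs, x$FG_star(Fs), lwd = 2)
  graphics::lines(Fs, x$FGcg_star(Fs), lwd = 2, col = "#d32f2f")
  graphics::legend("topright", c("[FG]", "[FG]cg"), lwd = 2,
                   col = c("black", "#d32f2f"), bty = "n")
  invisible(x)
}

#' Steady states of the emergent one-variable ODE
#'
#' Roots of `d[F]/dt = beta(1-F) - gamma F + alpha [FG]*(F) -
#' phi pf N (1-F) [FG]cg*(F)` located by sign-change bracketing on a fine
#' grid over the data-supported range of the fitted curves, refined with
#' `uniroot`. Stability follows from the sign of the numerical derivative
#' (negative slope = stable). Extrapolation beyond the fitted range is
#' refused; no sign change yields an empty result.
#'
#' @param curves an `fgba_curves` object.
#' @param params an [fgba_params()] object.
#' @param N cell count.
#' @param n_grid grid resolution for bracketing.
#' @return A data frame with columns `F_star` and `stable` (logical),
#'   possibly with zero rows.
#' @export
ode_steady_states <- function(curves, params, N, n_grid = 400) {
  stopifnot(inherits(curves, "fgba_curves"),
            inherits(params, "fgba_params"))
  pf <- spread_probabilities(params)[["pf"]]
  rhs <- function(F) {
    params$beta * (1 - F) - params$gamma * F +
      params$alpha * curves$FG_star(F) -
      params$phi * pf * N * (1 - F) * curves$FGcg_star(F)
  }
  Fs <- seq(curves$range[1], curves$range[2], length.out = n_grid)
  v <- rhs(Fs)
  roots <- numeric(0)
  for (i in seq_len(n_grid - 1)) {
    if (v[i] == 0) roots <- c(roots, Fs[i])
    if (v[i] * v[i + 1] < 0) {
      roots <- c(roots, stats::uniroot(rhs, c(Fs[i], Fs[i + 1]),
                                       tol = 1e-9)$root)
    }
  }
  if (length(v) && v[length(v)] == 0) roots <- c(roots, Fs[length(v)])
  roots <- sort(unique(roots))
  h <- diff(curves$range) / (4 * n_grid)
  stable <- vapply(roots, function(r) {
    lo <- max(curves$range[1], r - h)
    hi <- min(curves$range[2], r + h)
    (rhs(hi) - rhs(lo)) < 0
  }, logical(1))
  data.frame(F_star = roots, stable = stable)
}

#' Critical hole size for forest collapse without demography
#'
#' With `gamma = beta = 0`, a square grass hole carved into closed forest
#' either closes (forest spread wins) or grows without bound (fire wins).
#' Grass being a single cluster, the balance reduces to
#' `d[F]/dt = (alpha - phi N pf [G]) [FG]`, with unstable equilibrium at
#' `[F]c = 1 - alpha/(phi N pf)`; the critical hole size is its
#' complement, `[G]c = alpha / (phi N pf)`, capped at 1. Equivalently
#' `[G]c = phi1 / phi` where `phi1 = alpha / (N pf)` is the ignition rate
#' at which the whole domain is the critical hole (the lower limit of the
#' bistability range).
#'
#' @param params an [fgba_params()] object with `gamma = 0` and
#'   `beta = 0` (error otherwise: the expression is only valid without
#'   spontaneous demography).
#' @param N cell count.
#' @return The critical grass fraction, with attribute `phi1`.
#' @export
critical_hole_size <- function(params, N) {
  stopifnot(inherits(params, "fgba_params"))
  if (params$gamma != 0 || params$beta != 0) {
    stop("critical hole size is only valid for gamma = beta = 0")
  }
  pf <- spread_probabilities(params)[["pf"]]
  phiN <- params$phi * N
  if (phiN * pf <= 0) stop("phi * N * pf must be positive")
  gc <- min(1, params$alpha / (phiN * pf))
  attr(gc, "phi1") <- params$alpha / (N * pf)
  gc
}
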