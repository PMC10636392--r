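#' Feedback-control configuration
#'
#' Configuration of the noninvasive proportional feedback law
#' `phi(t) = phi0 + g ([F](t) - F_ref)` (clamped at 0) used to stabilise
#' saddle equilibria without shifting them: at a steady state
#' `[F] = F_ref + ([phi] - phi0)/g`, the realised `(phi, [F])` pair lies on
#' the equilibrium manifold of the uncontrolled system, so sweeping
#' `F_ref` traces the branch. With `g > 0`, excess forest raises fire
#' pressure, opposing divergence from `F_ref` (stabilising).
#'
#' Rates can be given per cell (`phi0`, `g`) or in domain-total units
#' (`phiN0`, `gN`, requiring `N`), matching the convention in which
#' ignition rates are usually quoted.
#'
#' @param phi0 base per-cell ignition rate (1/y).
#' @param g feedback gain (per-cell phi per unit `[F]`).
#' @param F_ref target forest fraction.
#' @param t0 burn-in before averaging (years).
#' @param T averaging window length (years), > 0.
#' @param phiN0,gN,N domain-total alternatives to `phi0` and `g`.
#' @return An `fgba_control_config` object (per-cell units).
#' @export
control_config <- function(phi0 = NULL, g = NULL, F_ref, t0 = 0, T = 1,
                           phiN0 = NULL, gN = NULL, N = NULL) {
  if (!is.null(phiN0) || !is.null(gN)) {
    if (is.null(N)) stop("domain-total rates require the cell count N")
    if (!is.null(phiN0)) phi0 <- phiN0 / N
    if (!is.null(gN)) g <- gN / N
  }
  if (is.null(phi0) || is.null(g)) stop("phi0 and g (or phiN0/gN) required")
  if (!is.finite(g)) stop("gain must be finite")
  if (T <= 0) stop("averaging window T must be positive")
  structure(list(phi0 = phi0, g = g, F_ref = F_ref, t0 = t0, T = T),
            class = "fgba_control_config")
}

#' Simulate under noninvasive feedback control
#'
#' Identical to [simulate_fgba()] except that the ignition propensity uses
#' the feedback law of the supplied [control_config()], re-evaluated after
#' every event that changes `[F]`; the trajectory records the effective
#' `phi(t)` at each record time. Warns when the clamp at `phi = 0` was
#' active more than half of the time (gain likely mis-set).
#'
#' @param landscape an `fgba_landscape`.
#' @param params an [fgba_params()] object; its `phi` is overridden by the
#'   control law (spread rates are unaffected).
#' @param cfg an [control_config()] object.
#' @param t_end simulated duration, must exceed `cfg$t0 + cfg$T`.
#' @param seed integer RNG seed.
#' @param ... further arguments passed to [simulate_fgba()].
#' @return An `fgba_trajectory`.
#' @export
controlled_simulate <- function(landscape, params, cfg, t_end, seed, ...) {
  stopifnot(inherits(cfg, "fgba_control_config"))
  if (t_end <= cfg$t0 + cfg$T) {
    stop("t_end must exceed the burn-in plus averaging window (t0 + T)")
  }
  simulate_fgba(landscape, params, t_end, seed, control = cfg, ...)
}

.window_integral <- function(tr, t0, t1, what = c("F", "G")) {
  what <- match.arg(what)
  if (t0 < tr$t[1] - 1e-9 || t1 > tr$t_final + 1e-9) {
    stop("averaging window not covered by the trajectory")
  }
  int <- tr[[paste0("int", what)]]
  if (!is.null(int) && length(int) == length(tr$t)) {
    # event-exact integrals recorded by the engine; linear interpolation
    # between record times is exact at record times themselves
    stats::approx(tr$t, int, xout = c(t0, t1), rule = 2)$y |>
      diff()
  } else {
    # piecewise-constant integral of the sampled series
    tt <- c(tr$t, tr$t_final)
    y <- tr[[what]]
    lo <- pmax(pmin(tt[-length(tt)], t1), t0)
    hi <- pmax(pmin(tt[-1], t1), t0)
    sum(y * (hi - lo))
  }
}

#' Equilibrium estimate from a (controlled) trajectory
#'
#' Time-averaged forest cover `F_bar = (1/T) int_{t0}^{t0+T} [F](t) dt`
#' (event-exact piecewise-constant integral, not a sample mean) and the
#' effective ignition rate `phi_bar = (n_ignitions / T) / G_bar`: the
#' realised per-grass-cell ignition rate over the window, which under
#' control is the steady `phi` the uncontrolled system would need to sit
#' at the same equilibrium.
#'
#' @param trajectory an `fgba_trajectory` (or a list with `t`, `F`, `G`,
#'   `t_final`, `ignition_times`, `N` for synthetic series; integrals are
#'   then taken piecewise-constant in the samples).
#' @param t0 window start (defaults to the control config's `t0`, else 0).
#' @param T window length (defaults to the config's `T`, else the rest of
#'   the trajectory).
#' @return Named vector `c(phiN_bar, F_bar, G_bar, n_ignitions)` where
#'   `phiN_bar = phi_bar * N` is in domain-total units.
#' @export
equilibrium_estimate <- function(trajectory, t0 = NULL, T = NULL) {
  cfg <- trajectory$control
  if (is.null(t0)) t0 <- if (!is.null(cfg)) cfg$t0 else 0
  if (is.null(T)) {
    T <- if (!is.null(cfg)) cfg$T else trajectory$t_final - t0
  }
  if (T <= 0) stop("window length must be positive")
  F_bar <- .window_integral(trajectory, t0, t0 + T, "F") / T
  G_bar <- .window_integral(trajectory, t0, t0 + T, "G") / T
  if (G_bar <= 0) stop("mean grass cover in the window is zero")
  n_ign <- sum(trajectory$ignition_times > t0 &
                 trajectory$ignition_times <= t0 + T)
  phi_bar <- (n_ign / T) / (G_bar * trajectory$N)
  c(phiN_bar = phi_bar * trajectory$N, F_bar = F_bar, G_bar = G_bar,
    n_ignitions = n_ign)
}

#' Moving-block bootstrap confidence interval for a mean
#'
#' Resamples overlapping blocks of length `block_length`, concatenates
#' them to the original length and recomputes the mean; the CI follows
#' from the bootstrap quantiles. Blocks preserve short-range
#' autocorrelation that an i.i.d. bootstrap would destroy.
#'
#' @param series numeric vector (length at least `2 * block_length`).
#' @param block_length block size in samples.
#' @param n_boot number of bootstrap replicates.
#' @param seed integer RNG seed.
#' @param level confidence level.
#' @return CI half-width, with attributes `ci` (the interval) and `mean`.
#' @export
block_bootstrap_ci <- function(series, block_length, n_boot = 1000,
                               seed = 1L, level = 0.95) {
  n <- length(series)
  if (n < 2 * block_length) {
    stop("series must be at least twice the block length")
  }
  set.seed(as.integer(seed))
  nb <- ceiling(n / block_length)
  n_starts <- n - block_length + 1
  means <- vapply(seq_len(n_boot), function(b) {
    starts <- sample.int(n_starts, nb, replace = TRUE)
    idx <- as.vector(outer(0:(block_length - 1), starts, `+`))[1:n]
    mean(series[idx])
  }, numeric(1))
  a <- (1 - level) / 2
  ci <- stats::quantile(means, c(a, 1 - a), names = FALSE)
  hw <- diff(ci) / 2
  attr(hw, "ci") <- ci
  attr(hw, "mean") <- mean(series)
  hw
}

#' Trace the bifurcation branch of equilibria
#'
#' Builds the diagram of steady-state forest cover against the ignition
#' rate `phi N`. Unstable (saddle) points come from feedback-controlled
#' runs swept over `F_ref` (each yielding a `(phiN_bar, F_bar)` estimate);
#' stable points come from regular simulations started at all-forest and
#' all-grass for each requested `phiN`. Every point carries a
#' moving-block-bootstrap CI on `F_bar`; a controlled run whose control
#' failed to settle (clamped more than half the time, or window sd of
#' `[F]` above 0.15) is flagged, not fabricated.
#'
#' @param params an [fgba_params()] object (its `phi` is only used for
#'   the stable runs when `phiN_stable` is NULL).
#' @param F_ref numeric vector of control targets for the unstable branch
#'   (may be empty).
#' @param gains domain-total control gains `gN`, recycled over `F_ref`;
#'   must be non-empty when `F_ref` is.
#' @param phiN0 base domain-total ignition rate for the controlled runs.
#' @param phiN_stable ignition rates at which to measure stable points.
#' @param width,height lattice dimensions.
#' @param t0,T burn-in and averaging window (years).
#' @param seed integer seed root.
#' @param record_dt recording cadence.
#' @param block_length bootstrap block length in records.
#' @param init_f optional initial forest fraction for controlled runs
#'   (defaults to `F_ref`).
#' @return An `fgba_branch` data frame with columns `phiN_bar`, `F_bar`,
#'   `stability`, `ci_lo`, `ci_hi`, `g`, `seed`, `converged`, sorted by
#'   `phiN_bar`.
#' @export
trace_branch <- function(params, F_ref = numeric(0), gains = NULL,
                         phiN0 = NULL, phiN_stable = numeric(0),
                         width = 50, height = width,
                         t0 = 100, T = 150, seed = 1L, record_dt = 0.5,
                         block_length = 50, init_f = NULL) {
  N <- width * height
  if (length(F_ref) > 0) {
    if (is.null(gains) || length(gains) == 0) {
      stop("controlled points require at least one gain")
    }
    if (is.null(phiN0)) stop("controlled points require phiN0")
    gains <- rep_len(gains, length(F_ref))
  }
  rows <- list()
  k <- 0L
  point <- function(tr, stability, g) {
    est <- equilibrium_estimate(tr, t0, T)
    in_win <- tr$t >= t0 & tr$t <= t0 + T
    hw <- block_bootstrap_ci(tr$F[in_win], block_length,
                             seed = tr$seed + 1L)
    conv <- !tr$truncated &&
      (is.null(tr$control) || tr$clamped_time < 0.5 * tr$t_final) &&
      stats::sd(tr$F[in_win]) < 0.15
    data.frame(phiN_bar = est[["phiN_bar"]], F_bar = est[["F_bar"]],
               stability = stability,
               ci_lo = est[["F_bar"]] - hw, ci_hi = est[["F_bar"]] + hw,
               g = g, seed = tr$seed, converged = conv)
  }
  for (i in seq_along(F_ref)) {
    k <- k + 1L
    f0 <- if (is.null(init_f)) F_ref[i] else init_f
    ls <- initial_landscape("uniform_random", width, height, f = f0,
                            seed = as.integer(seed) + 37L * k)
    cfg <- control_config(phiN0 = phiN0, gN = gains[i], N = N,
                          F_ref = F_ref[i], t0 = t0, T = T)
    tr <- controlled_simulate(ls, params, cfg, t_end = t0 + T + record_dt,
                              seed = as.integer(seed) + 101L * k,
                              record_dt = record_dt)
    rows[[length(rows) + 1L]] <- point(tr, "unstable", gains[i])
  }
  for (phiN in phiN_stable) {
    p <- fgba_params(alpha = params$alpha, beta = params$beta,
                     gamma = params$gamma, phiN = phiN, N = N,
                     lambda = params$lambda, mu = params$mu,
                     rho_g = params$rho_g, rho_f = params$rho_f,
                     check = FALSE)
    for (init in c("all_forest", "all_grass")) {
      k <- k + 1L
      ls <- initial_landscape(init, width, height)
      tr <- simulate_fgba(ls, p, t_end = t0 + T + record_dt,
                          seed = as.integer(seed) + 101L * k,
                          record_dt = record_dt)
      rows[[length(rows) + 1L]] <- point(tr, "stable", NA_real_)
    }
  }
  br <- do.call(rbind, rows)
  br <- br[order(br$phiN_bar), ]
  rownames(br) <- NULL
  class(br) <- c("fgba_branch", "data.frame")
  attr(br, "meta") <- list(t0 = t0, T = T, width = width, height = height,
                           seed = seed)
  br
}

#' @export
plot.fgba_branch <- function(x, ...) {
  plot(x$phiN_bar, x$F_bar, pch = ifelse(x$stability == "stable", 16, 1),
       col = ifelse(x$stability == "stable", "black", "#d32f2f"),
       xlab = expression(phi * N ~ (1 / y)), ylab = "[F]",
       ylim = c(0, 1), ...)
  graphics::segments(x$phiN_bar, x$ci_lo, x$phiN_bar, x$ci_hi,
                     col = "#00000060")
  graphics::legend("topright", c("stable", "unstable (controlled)"),
                   pch = c(16, 1), col = c("black", "#d32f2f"), bty = "n")
  invisible(x)
}
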