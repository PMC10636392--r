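#' Exact stochastic simulation of the FGBA automaton
#'
#' Samples a statistically exact realisation of the continuous-time Markov
#' chain defined by the reaction rules: spontaneous `G->F`, `A->F` (beta),
#' `F->G` (gamma), `G->B` (phi), `B->A` (mu), `A->G` (lambda), and
#' neighbour-driven `G->F`, `A->F` (alpha per F neighbour), `G->B` (rho_g
#' per B neighbour), `F->B` (rho_f per B neighbour). The implementation is
#' an event-driven direct method with per-cell propensities in a Fenwick
#' tree (propensity updates are local to the event's neighbourhood) and
#' compensated time summation, so runs that interleave ~1e6/y fire events
#' with ~1e-2/y demography remain exact and fast.
#'
#' State fractions are recorded on a fixed time grid (`record_dt`), which
#' is decoupled from the event stream; exact running time-integrals of
#' `[F]` and `[G]` are recorded alongside so that window averages can be
#' computed event-exactly (see [equilibrium_estimate()]). Ignition
#' timestamps and per-channel event counts are always logged.
#'
#' @param landscape an `fgba_landscape` initial condition.
#' @param params an [fgba_params()] object.
#' @param t_end simulated duration (years), > 0.
#' @param seed integer RNG seed; the trajectory is reproducible from it.
#' @param record_dt recording cadence (years).
#' @param record_pairs if `TRUE`, also record `[FG]` and `[FG]cg` at each
#'   record time (costs one cluster labelling per record).
#' @param snapshot_times numeric vector of times at which to store full
#'   landscape snapshots.
#' @param control optional [control_config()]; when supplied the ignition
#'   rate follows the feedback law `phi(t) = phi0 + g([F](t) - F_ref)`,
#'   clamped at 0, re-evaluated after every event.
#' @param stop_when_no_burning stop as soon as no cell is burning (used by
#'   the single-fire analysis).
#' @param track_burn record which cells ever burned.
#' @param track_occupancy accumulate time spent in each full lattice state
#'   (tiny lattices only, N <= 12); used for exactness checks against the
#'   brute-force CTMC generator.
#' @param max_events safety cap on the number of events; the trajectory is
#'   flagged `truncated` if reached.
#' @return An `fgba_trajectory`: list with record vectors `t`, `F`, `G`,
#'   `B`, `A`, `phi`, `intF`, `intG`, optional `FG`/`FGcg`, event `counts`,
#'   `ignition_times`, `final` landscape, `snapshots`, `t_final`,
#'   `n_events`, `seed`, `params`, and bookkeeping fields.
#' @examples
#' ls <- initial_landscape("all_grass", 20, 20)
#' p <- fgba_params(phiN = 0.075, N = 400)
#' tr <- simulate_fgba(ls, p, t_end = 5, seed = 1)
#' tail(tr$F, 1)
#' @export
simulate_fgba <- function(landscape, params, t_end, seed,
                          record_dt = 0.5, record_pairs = FALSE,
                          snapshot_times = numeric(0), control = NULL,
                          stop_when_no_burning = FALSE,
                          track_burn = FALSE, track_occupancy = FALSE,
                          max_events = Inf) {
  stopifnot(inherits(landscape, "fgba_landscape"),
            inherits(params, "fgba_params"))
  if (!is.numeric(t_end) || t_end <= 0) stop("t_end must be positive")
  ctrl_on <- !is.null(control)
  if (ctrl_on) stopifnot(inherits(control, "fgba_control_config"))
  set.seed(as.integer(seed))
  phi0 <- if (ctrl_on) control$phi0 else params$phi
  res <- cpp_simulate(as.integer(landscape$cells),
                      landscape$width, landscape$height,
                      params$alpha, params$beta, params$gamma, phi0,
                      params$lambda, params$mu, params$rho_g, params$rho_f,
                      as.numeric(t_end), as.numeric(record_dt),
                      as.numeric(snapshot_times), record_pairs,
                      ctrl_on,
                      if (ctrl_on) control$g else 0,
                      if (ctrl_on) control$F_ref else 0,
                      stop_when_no_burning, track_burn, track_occupancy,
                      TRUE, as.numeric(max_events))
  snaps <- lapply(res$snapshots, function(s) {
    as_landscape(matrix(s, landscape$height, landscape$width))
  })
  tr <- list(t = res$t, F = res$F, G = res$G, B = res$B, A = res$A,
             phi = res$phi, intF = res$intF, intG = res$intG,
             FG = if (record_pairs) res$FG else NULL,
             FGcg = if (record_pairs) res$FGcg else NULL,
             counts = res$counts, ignition_times = res$ignition_times,
             final = as_landscape(matrix(res$final, landscape$height,
                                         landscape$width)),
             snapshots = snaps, snapshot_times = res$snapshot_times,
             t_final = res$t_final, n_events = res$n_events,
             truncated = res$truncated, clamped_time = res$clamped_time,
             ever_burned = res$ever_burned,
             occupancy = if (track_occupancy) {
               stats::setNames(res$occupancy_times,
                               format(res$occupancy_codes, scientific = FALSE,
                                      trim = TRUE))
             } else NULL,
             width = landscape$width, height = landscape$height,
             N = landscape$N, seed = as.integer(seed),
             params = params, control = control,
             record_dt = record_dt)
  class(tr) <- "fgba_trajectory"
  if (res$truncated) {
    warning("simulation truncated at max_events before t_end", call. = FALSE)
  }
  if (ctrl_on && res$t_final > 0 &&
      res$clamped_time > 0.5 * res$t_final) {
    warning("feedback-controlled phi was clamped at 0 for more than half ",
            "of the run; the gain is probably mis-set", call. = FALSE)
  }
  tr
}

#' @export
print.fgba_trajectory <- function(x, ...) {
  cat(sprintf("FGBA trajectory: %d x %d lattice, t in [0, %.3g] y, %d records, %.0f events (seed %d)\n",
              x$width, x$height, x$t_final, length(x$t), x$n_events, x$seed))
  fr <- state_fractions(x$final)
  cat(sprintf("  final: [F]=%.4f [G]=%.4f [B]=%.4f [A]=%.4f; ignitions: %d\n",
              fr["F"], fr["G"], fr["B"], fr["A"], length(x$ignition_times)))
  invisible(x)
}

#' @export
plot.fgba_trajectory <- function(x, which = c("F", "G", "B", "A"), ...) {
  cols <- c(F = "#1b5e20", G = "#c0a200", B = "#d32f2f", A = "#757575")
  graphics::matplot(x$t, do.call(cbind, x[which]), type = "l", lty = 1,
                    col = cols[which], xlab = "time (y)",
                    ylab = "cover fraction", ...)
  graphics::legend("topright", legend = which, col = cols[which],
                   lty = 1, bty = "n")
  invisible(x)
}

#' Ensemble of independent replicate simulations
#'
#' Runs `n_reps` independent replicates with seeds derived
#' deterministically from `base_seed` (replicate i uses
#' `base_seed + 1009 * i`).
#'
#' @param landscape initial `fgba_landscape` (shared by all replicates).
#' @param params an [fgba_params()] object.
#' @param t_end simulated duration (years).
#' @param n_reps number of replicates (0 gives an empty list).
#' @param base_seed integer seed root.
#' @param ... further arguments passed to [simulate_fgba()].
#' @return List of `fgba_trajectory` objects.
#' @export
run_ensemble <- function(landscape, params, t_end, n_reps, base_seed, ...) {
  if (n_reps < 0) stop("n_reps must be >= 0")
  lapply(seq_len(n_reps), function(i) {
    simulate_fgba(landscape, params, t_end,
                  seed = as.integer(base_seed) + 1009L * i, ...)
  })
}
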