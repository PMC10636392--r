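#' Simulate a single fire event on a frozen landscape
#'
#' Runs the fast fire subprocess in isolation: starting from one ignited
#' grass cell, the full CTMC restricted to the channels `G->B` (spread at
#' `rho_g` per burning neighbour), `F->B` (spread at `rho_f` per burning
#' neighbour) and `B->A` (extinction at `mu`) is simulated until no cell
#' burns. Vegetation dynamics (`alpha`, `beta`, `gamma`, `lambda`, `phi`)
#' are frozen, matching the timescale separation under which a fire sees a
#' static landscape. Burning forest cells do spread fire onward here — the
#' analytic approximation in [expected_fire_loss()] neglects that, so the
#' pair gives an approximation-versus-truth comparison.
#'
#' @param landscape an `fgba_landscape`; the ignition cell must hold G.
#' @param params an [fgba_params()] object (only `rho_g`, `rho_f`, `mu`
#'   are used).
#' @param ignition_cell either a linear (column-major) cell index or a
#'   `c(row, col)` pair.
#' @param seed integer RNG seed.
#' @return An `fgba_fire_event`: list with `ignition_cell`, `cluster`
#'   (index of the ignited grass cluster), `burned` (linear indices of all
#'   cells that burned), `burned_grass`, `burned_forest`,
#'   `forest_lost` (count), `forest_lost_frac` (/N), `duration` (years),
#'   and the post-fire `landscape` (burned cells are ash).
#' @export
simulate_fire_event <- function(landscape, params, ignition_cell, seed) {
  stopifnot(inherits(landscape, "fgba_landscape"),
            inherits(params, "fgba_params"))
  if (length(ignition_cell) == 2) {
    ignition_cell <- (ignition_cell[2] - 1L) * landscape$height +
      ignition_cell[1]
  }
  ignition_cell <- as.integer(ignition_cell)
  if (ignition_cell < 1 || ignition_cell > landscape$N) {
    stop("ignition cell outside the lattice")
  }
  if (landscape$cells[ignition_cell] != 1L) {
    stop("ignition cell must hold grass (G)")
  }
  decomp <- grass_clusters(landscape)
  j <- decomp$labels[ignition_cell]
  fire_params <- fgba_params(alpha = 0, beta = 0, gamma = 0, phi = 0,
                             lambda = 0, mu = params$mu,
                             rho_g = params$rho_g, rho_f = params$rho_f,
                             check = FALSE)
  cells <- landscape$cells
  cells[ignition_cell] <- 2L
  tr <- simulate_fgba(as_landscape(cells), fire_params,
                      t_end = 1, # fires last ~ 1/mu << 1 y; stop on no-B
                      seed = seed, record_dt = 1,
                      stop_when_no_burning = TRUE, track_burn = TRUE)
  burned <- which(tr$ever_burned)
  was_forest <- landscape$cells[burned] == 0L
  structure(list(ignition_cell = ignition_cell, cluster = j,
                 burned = burned,
                 burned_grass = burned[!was_forest],
                 burned_forest = burned[was_forest],
                 forest_lost = sum(was_forest),
                 forest_lost_frac = sum(was_forest) / landscape$N,
                 duration = tr$t_final,
                 landscape = tr$final),
            class = "fgba_fire_event")
}

#' @export
print.fgba_fire_event <- function(x, ...) {
  cat(sprintf("fire event: cluster %d, %d cells burned (%d forest), duration %.3g y\n",
              x$cluster, length(x$burned), x$forest_lost, x$duration))
  invisible(x)
}

#' Burn probability of an interface forest cell
#'
#' A forest cell with `fg_ij` grass neighbours in the burning cluster is
#' ignited with probability `1 - (1 - pf)^fg_ij` when each exposure is an
#' independent chance `pf` (exact form), or `pf * fg_ij` in the
#' small-`pf` linearisation.
#'
#' @param fg_ij number of exposures (grass neighbours in the cluster),
#'   0 to 4.
#' @param pf fire spread probability into forest, in `[0, 1]`.
#' @param linearized return the linearised form `pf * fg_ij`.
#' @return Probability (the linearised form can exceed 1).
#' @examples
#' forest_cell_burn_probability(2, 0.1)        # 0.19
#' forest_cell_burn_probability(2, 0.1, TRUE)  # 0.20
#' @export
forest_cell_burn_probability <- function(fg_ij, pf, linearized = FALSE) {
  if (any(pf < 0 | pf > 1)) stop("pf must be in [0, 1]")
  if (any(fg_ij < 0 | fg_ij > 4)) stop("fg_ij must be in 0..4")
  if (linearized) pf * fg_ij else 1 - (1 - pf)^fg_ij
}

#' Expected forest loss from one fire in a grass cluster
#'
#' The expected number of forest cells lost when a fire burns the whole of
#' grass cluster `j`: linearised form `pf * [FG]_j` (per the balance
#' equation's loss term), or the exact-exposure form summing
#' `1 - (1 - pf)^[FG]_ij` over interface forest cells. Both are normalised
#' by N, matching `[FG]_j`. The approximation assumes the fire reaches the
#' whole interface exactly once (`pg -> 1`) and that burning forest does
#' not spread onward (small `pf`); a warning flags `pg < 0.9` when
#' `params` is supplied.
#'
#' @param decomp an `fgba_clusters` decomposition.
#' @param j cluster index.
#' @param pf fire spread probability into forest.
#' @param method `"linear"` (default) or `"exact"`.
#' @param params optional [fgba_params()]; if given, used only to check
#'   the `pg -> 1` validity assumption.
#' @return Expected loss as a fraction of the domain.
#' @export
expected_fire_loss <- function(decomp, j, pf,
                               method = c("linear", "exact"),
                               params = NULL) {
  stopifnot(inherits(decomp, "fgba_clusters"))
  method <- match.arg(method)
  if (pf < 0 || pf > 1) stop("pf must be in [0, 1]")
  if (j < 1 || j > decomp$nc) stop("invalid cluster index")
  if (!is.null(params)) {
    pg <- spread_probabilities(params)["pg"]
    if (pg < 0.9) {
      warning(sprintf(
        "pg = %.3f < 0.9: the whole-interface assumption is doubtful", pg),
        call. = FALSE)
    }
  }
  if (method == "linear") return(pf * decomp$fg[j])
  sum(forest_cell_burn_probability(interface_exposures(decomp, j), pf)) /
    decomp$N
}

#' Per-forest-cell exposure counts at a cluster interface
#'
#' For grass cluster `j`, the number of cluster-`j` grass neighbours
#' (`[FG]_ij`, 1..4) of each interface forest cell. Their sum is the raw
#' `[FG]_j` pair count.
#'
#' @param decomp an `fgba_clusters` decomposition.
#' @param j cluster index.
#' @return Integer vector, one entry per interface forest cell.
#' @export
interface_exposures <- function(decomp, j) {
  stopifnot(inherits(decomp, "fgba_clusters"))
  if (j < 1 || j > decomp$nc) stop("invalid cluster index")
  ls <- decomp$landscape
  h <- ls$height
  w <- ls$width
  lab <- decomp$labels
  # count, for every forest cell, neighbours in cluster j via shifts
  injm <- matrix(as.integer(lab == j), h, w)
  up <- injm[c(2:h, 1), , drop = FALSE]
  dn <- injm[c(h, 1:(h - 1)), , drop = FALSE]
  lf <- injm[, c(2:w, 1), drop = FALSE]
  rt <- injm[, c(w, 1:(w - 1)), drop = FALSE]
  expo <- up + dn + lf + rt
  expo <- expo[ls$cells == 0L]
  as.integer(expo[expo > 0])
}
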