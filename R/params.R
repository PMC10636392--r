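#' Rate parameters of the FGBA automaton
#'
#' Bundles the eight rate constants of the forest-grass-burning-ash lattice
#' automaton (all in 1/year). Spontaneous channels: recruitment `G,A -> F` at
#' `beta`, mortality `F -> G` at `gamma`, ignition `G -> B` at `phi` (per
#' grass cell), grass regrowth `A -> G` at `lambda`, fire extinction
#' `B -> A` at `mu`. Neighbour channels (per neighbour connection of the
#' indicated type): forest spread `GF,AF -> FF` at `alpha`, fire spread
#' `GB -> BB` at `rho_g` and `FB -> BB` at `rho_f`.
#'
#' Defaults are the reference parameterisation used throughout the package:
#' `alpha = 3e-2`, `beta = 2e-4`, `gamma = 2e-2`, `lambda = 5`, `mu = 1e6`,
#' `rho_g = 9e6`, `rho_f = 1.11e5`, which give fire spread probabilities
#' `pg = 0.9` and `pf ~ 0.1` (see [spread_probabilities()]).
#'
#' The ignition rate may be given per cell (`phi`) or as the domain-total
#' rate `phiN` together with the cell count `N`; the object always stores
#' the per-cell rate, and figures/analyses conventionally quote `phi * N`.
#'
#' @param alpha forest spread rate per GF/AF neighbour pair (1/y).
#' @param beta spontaneous forest recruitment rate on G or A cells (1/y).
#' @param gamma spontaneous forest mortality rate (1/y).
#' @param phi per-cell fire ignition rate on grass (1/y). Ignored when
#'   `phiN` is given.
#' @param phiN optional domain-total ignition rate; requires `N`.
#' @param N cell count used to convert `phiN` to a per-cell rate.
#' @param lambda grass regrowth rate on ash (1/y).
#' @param mu fire extinction rate (1/y).
#' @param rho_g fire spread rate per GB neighbour pair (1/y).
#' @param rho_f fire spread rate per FB neighbour pair (1/y).
#' @param check if `TRUE`, warn when the fast/slow timescale ordering
#'   (`rho_g, mu > rho_f >> 1 >> alpha, beta, gamma`) is violated. The
#'   ordering underpins the fast-slow analysis; violating it is allowed
#'   (e.g. for exactness tests on tiny lattices) but worth flagging.
#'
#' @return An object of class `fgba_params` (a named list of rates).
#' @examples
#' p <- fgba_params(phiN = 0.257, N = 2500)
#' spread_probabilities(p)
#' @export
fgba_params <- function(alpha = 3e-2, beta = 2e-4, gamma = 2e-2,
                        phi = 1e-4, phiN = NULL, N = NULL,
                        lambda = 5, mu = 1e6, rho_g = 9e6, rho_f = 1.11e5,
                        check = TRUE) {
  if (!is.null(phiN)) {
    if (is.null(N)) stop("supplying 'phiN' requires the cell count 'N'")
    phi <- phiN / N
  }
  p <- list(alpha = alpha, beta = beta, gamma = gamma, phi = phi,
            lambda = lambda, mu = mu, rho_g = rho_g, rho_f = rho_f)
  bad <- vapply(p, function(x) !is.numeric(x) || length(x) != 1 ||
                  is.na(x) || x < 0, logical(1))
  if (any(bad)) {
    stop("rates must be single non-negative numbers; offending: ",
         paste(names(p)[bad], collapse = ", "))
  }
  class(p) <- "fgba_params"
  if (check) {
    slow <- max(p$alpha, p$beta, p$gamma)
    ok <- (min(p$rho_g, p$mu) >= p$rho_f) &&
      (p$rho_f >= 100) &&
      (slow <= 0.1) &&
      (p$lambda >= 10 * slow)
    if (!ok) {
      warning("rates violate the fast/slow timescale ordering ",
              "(rho_g, mu > rho_f >> 1/y >> alpha, beta, gamma); ",
              "fast-slow approximations may not apply", call. = FALSE)
    }
  }
  p
}

#' Fire spread probabilities
#'
#' Probability that a burning cell ignites a given neighbouring grass
#' (`pg = rho_g / (rho_g + mu)`) or forest (`pf = rho_f / (rho_f + mu)`)
#' cell before it extinguishes. These are the only combinations in which
#' the fast rates enter the slow dynamics.
#'
#' @param params an [fgba_params()] object.
#' @return Named numeric vector `c(pg = , pf = )`.
#' @examples
#' spread_probabilities(fgba_params())  # pg = 0.9, pf ~ 0.1
#' @export
spread_probabilities <- function(params) {
  stopifnot(inherits(params, "fgba_params"))
  if (params$rho_g + params$mu <= 0) {
    stop("rho_g + mu must be positive to define pg")
  }
  if (params$rho_f + params$mu <= 0) {
    stop("rho_f + mu must be positive to define pf")
  }
  c(pg = params$rho_g / (params$rho_g + params$mu),
    pf = params$rho_f / (params$rho_f + params$mu))
}

#' @export
print.fgba_params <- function(x, ...) {
  cat("FGBA rate parameters (1/y):\n")
  cat(sprintf("  alpha = %g  beta = %g  gamma = %g  phi = %g\n",
              x$alpha, x$beta, x$gamma, x$phi))
  cat(sprintf("  lambda = %g  mu = %g  rho_g = %g  rho_f = %g\n",
              x$lambda, x$mu, x$rho_g, x$rho_f))
  sp <- spread_probabilities(x)
  cat(sprintf("  spread probabilities: pg = %.4f, pf = %.4f\n",
              sp["pg"], sp["pf"]))
  invisible(x)
}
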