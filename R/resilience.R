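#' Perturbation specification
#'
#' Describes a landscape perturbation of one of four kinds mirroring the
#' natural processes: `remove_perimeter_forest` (forest cells bordering
#' the largest grass cluster converted to grass, as a fire would),
#' `add_perimeter_forest` (grass cells of the largest cluster bordering
#' forest converted to forest, as forest spread would),
#' `random_mortality` (random forest cells to grass) and
#' `random_recruitment` (random grass cells to forest). The weight is the
#' rate/probability with which the corresponding natural process occurs,
#' used by [mean_sensitivity()].
#'
#' @param kind one of the four kinds above.
#' @param magnitude fraction of eligible cells to convert, in `(0, 1]`.
#' @param weight non-negative ensemble weight.
#' @return An `fgba_perturbation` spec.
#' @export
perturbation_spec <- function(kind = c("remove_perimeter_forest",
                                       "add_perimeter_forest",
                                       "random_mortality",
                                       "random_recruitment"),
                              magnitude, weight = 1) {
  kind <- match.arg(kind)
  if (magnitude <= 0 || magnitude > 1) stop("magnitude must be in (0, 1]")
  if (weight < 0) stop("weight must be >= 0")
  structure(list(kind = kind, magnitude = magnitude, weight = weight),
            class = "fgba_perturbation")
}

.largest_grass_cluster <- function(decomp) {
  # ties broken by lowest cluster index (deterministic row-major labelling)
  which.max(decomp$sizes)
}

#' Apply a perturbation to a landscape
#'
#' Returns the perturbed landscape; deterministic given `seed`. The number
#' of converted cells is `max(1, round(magnitude * n_eligible))`, so a
#' vanishing magnitude still flips one cell.
#'
#' @param landscape an `fgba_landscape`.
#' @param spec an [perturbation_spec()] object.
#' @param seed integer RNG seed.
#' @return The perturbed `fgba_landscape`.
#' @export
apply_perturbation <- function(landscape, spec, seed = 1L) {
  stopifnot(inherits(landscape, "fgba_landscape"),
            inherits(spec, "fgba_perturbation"))
  cells <- landscape$cells
  eligible <- switch(spec$kind,
    remove_perimeter_forest = {
      decomp <- grass_clusters(landscape)
      if (decomp$nc == 0) integer(0) else {
        j <- .largest_grass_cluster(decomp)
        .forest_bordering_cluster(landscape, decomp, j)
      }
    },
    add_perimeter_forest = {
      decomp <- grass_clusters(landscape)
      if (decomp$nc == 0) integer(0) else {
        j <- .largest_grass_cluster(decomp)
        .grass_bordering_forest(landscape, decomp, j)
      }
    },
    random_mortality = which(cells == 0L),
    random_recruitment = which(cells == 1L))
  if (length(eligible) == 0) stop("empty eligible cell set for ", spec$kind)
  n <- max(1L, round(spec$magnitude * length(eligible)))
  n <- min(n, length(eligible))
  set.seed(as.integer(seed))
  chosen <- if (n == length(eligible)) eligible else sample(eligible, n)
  new_state <- switch(spec$kind,
                      remove_perimeter_forest = 1L,
                      add_perimeter_forest = 0L,
                      random_mortality = 1L,
                      random_recruitment = 0L)
  cells[chosen] <- new_state
  as_landscape(cells)
}

.forest_bordering_cluster <- function(landscape, decomp, j) {
  expo <- .neighbour_count(decomp$labels == j, landscape)
  which(landscape$cells == 0L & expo > 0)
}

.grass_bordering_forest <- function(landscape, decomp, j) {
  nf <- .neighbour_count(landscape$cells == 0L, landscape)
  which(decomp$labels == j & nf > 0)
}

.neighbour_count <- function(mask, landscape) {
  h <- landscape$height
  w <- landscape$width
  m <- matrix(as.integer(mask), h, w)
  m[c(2:h, 1), ] + m[c(h, 1:(h - 1)), ] + m[, c(2:w, 1)] + m[, c(w, 1:(w - 1))]
}

#' Sensitivity of the forest balance to a perturbation
#'
#' The ratio `lambda_F = (net(X + dX) - net(X)) / ([F](X + dX) - [F](X))`
#' of the change in the balance-equation rate to the change in forest
#' cover. Negative values mean the perturbation is dampened (negative
#' feedback), positive values that it is amplified (positive feedback).
#' Both landscapes are evaluated through the slow-timescale vegetation
#' view for consistency with the balance equation.
#'
#' @param landscape,perturbed `fgba_landscape` objects (before and after
#'   the perturbation).
#' @param params an [fgba_params()] object.
#' @return The sensitivity (1/y).
#' @export
sensitivity <- function(landscape, perturbed, params) {
  b0 <- net_rate(landscape, params)
  b1 <- net_rate(perturbed, params)
  dF <- b1$F - b0$F
  if (dF == 0) stop("perturbation does not change [F]")
  (b1$net - b0$net) / dF
}

#' Ensemble-averaged sensitivity
#'
#' Averages the sensitivity over an ensemble of perturbations as the ratio
#' of weighted sums, `lambda_bar = sum_i w_i dnet_i / sum_i w_i dF_i`
#' (not the weighted mean of per-perturbation ratios), which estimates the
#' derivative of the emergent one-variable dynamics at the landscape's
#' `[F]`. Each spec is realised `n_realizations` times with seeds derived
#' from `seed`.
#'
#' @param landscape an `fgba_landscape`.
#' @param specs a list of [perturbation_spec()] objects (weights not all
#'   zero).
#' @param params an [fgba_params()] object.
#' @param n_realizations realisations per spec (default 64).
#' @param seed integer seed root.
#' @return The averaged sensitivity, with attribute `breakdown`: a data
#'   frame of per-realisation `kind`, `weight`, `dF` and `dnet`.
#' @export
mean_sensitivity <- function(landscape, specs, params,
                             n_realizations = 64, seed = 1L) {
  if (inherits(specs, "fgba_perturbation")) specs <- list(specs)
  stopifnot(length(specs) >= 1,
            all(vapply(specs, inherits, logical(1), "fgba_perturbation")))
  w_all <- vapply(specs, `[[`, numeric(1), "weight")
  if (all(w_all == 0)) stop("at least one spec must have positive weight")
  b0 <- net_rate(landscape, params)
  rows <- list()
  k <- 0L
  for (s in seq_along(specs)) {
    for (r in seq_len(n_realizations)) {
      k <- k + 1L
      pert <- apply_perturbation(landscape, specs[[s]],
                                 seed = as.integer(seed) + 7919L * k)
      b1 <- net_rate(pert, params)
      rows[[k]] <- data.frame(kind = specs[[s]]$kind,
                              weight = specs[[s]]$weight,
                              dF = b1$F - b0$F, dnet = b1$net - b0$net)
    }
  }
  br <- do.call(rbind, rows)
  den <- sum(br$weight * br$dF)
  if (den == 0) stop("weighted perturbations do not change [F] on average")
  out <- sum(br$weight * br$dnet) / den
  attr(out, "breakdown") <- br
  out
}

#' Default perturbation ensemble
#'
#' The four perturbation kinds with weights proportional to the rates of
#' the natural processes they mimic: fire-driven perimeter loss
#' (`phi N [G] pf [FG]cg`-scaled, here simply `phiN * pf`), forest spread
#' (`alpha`), mortality (`gamma`) and recruitment (`beta`).
#'
#' Magnitudes default to 0.1 for the perimeter kinds and 0.01 for the
#' scattered kinds, so each kind changes `[F]` by a comparable small
#' fraction and the perturbed landscapes stay close to dynamically
#' generated geometry (large scattered perturbations create artificially
#' fragmented landscapes far off the emergent manifold).
#'
#' @param params an [fgba_params()] object.
#' @param N cell count.
#' @param magnitude fraction of eligible cells the perimeter
#'   perturbations convert.
#' @param magnitude_random fraction converted by the scattered
#'   mortality/recruitment perturbations.
#' @return A list of [perturbation_spec()] objects.
#' @export
default_perturbations <- function(params, N, magnitude = 0.1,
                                  magnitude_random = 0.01) {
  pf <- spread_probabilities(params)[["pf"]]
  list(perturbation_spec("remove_perimeter_forest", magnitude,
                         weight = params$phi * N * pf),
       perturbation_spec("add_perimeter_forest", magnitude,
                         weight = params$alpha),
       perturbation_spec("random_mortality", magnitude_random,
                         weight = params$gamma),
       perturbation_spec("random_recruitment", magnitude_random,
                         weight = params$beta))
}
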