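.config_defaults <- function() {
  list(alpha = 3e-2, beta = 2e-4, gamma = 2e-2, phi = 1e-4, phiN = NULL,
       lambda = 5, mu = 1e6, rho_g = 9e6, rho_f = 1.11e5,
       width = 100, height = 100, init = "all_grass", f = 0.5,
       hole_fraction = 0.25, t_end = 100, record_dt = 0.5, seed = 1,
       out = NULL)
}

#' Load or save a run configuration
#'
#' YAML run configuration with the reference rates as defaults for any
#' omitted entry. Recognised keys: the eight rates (`alpha`, `beta`,
#' `gamma`, `phi` or `phiN`, `lambda`, `mu`, `rho_g`, `rho_f`) and the run
#' settings `width`, `height`, `init`, `f`, `hole_fraction`, `t_end`,
#' `record_dt`, `seed`, `out`. Unknown keys and negative rates are
#' errors. `save_config`/`load_config` round-trip losslessly.
#'
#' @param path YAML file path.
#' @return `load_config` returns an `fgba_config` list with a `params`
#'   element ([fgba_params()], `phiN` converted using `width * height`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  as_config(user)
}

#' @rdname load_config
#' @param config a config list (possibly partial).
#' @export
as_config <- function(config = list()) {
  def <- .config_defaults()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(def, config)
  rates <- c("alpha", "beta", "gamma", "phi", "lambda", "mu",
             "rho_g", "rho_f")
  for (r in rates) {
    if (!is.numeric(cfg[[r]]) || cfg[[r]] < 0) {
      stop("rate '", r, "' must be a non-negative number")
    }
  }
  N <- cfg$width * cfg$height
  cfg$params <- fgba_params(alpha = cfg$alpha, beta = cfg$beta,
                            gamma = cfg$gamma, phi = cfg$phi,
                            phiN = cfg$phiN, N = N,
                            lambda = cfg$lambda, mu = cfg$mu,
                            rho_g = cfg$rho_g, rho_f = cfg$rho_f,
                            check = FALSE)
  class(cfg) <- "fgba_config"
  cfg
}

#' @rdname load_config
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "fgba_config"))
  out <- unclass(config)
  out$params <- NULL
  out <- out[!vapply(out, is.null, logical(1))]
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Deterministic test fixtures
#'
#' Small hand-verifiable landscapes with a sidecar of expected metrics
#' (state fractions, pair densities, cluster structure) for test suites
#' and demonstrations. Available names: `"single_forest_cell_4x4"`,
#' `"checkerboard_8x8"`, `"two_cluster_demo"`, `"block_with_hole_10x10"`.
#'
#' @param name fixture name.
#' @return A list with `landscape` (an `fgba_landscape`) and `expected`
#'   (a list of hand-counted metric values).
#' @export
make_fixture <- function(name) {
  switch(name,
    single_forest_cell_4x4 = {
      m <- matrix(1L, 4, 4)
      m[2, 2] <- 0L
      list(landscape = as_landscape(m),
           expected = list(F = 1 / 16, G = 15 / 16, FG = 4 / 16,
                           nc = 1, FGcg = 4 / 16))
    },
    checkerboard_8x8 = {
      m <- outer(1:8, 1:8, `+`) %% 2L
      list(landscape = as_landscape(m),
           expected = list(F = 0.5, G = 0.5, nc = 32,
                           g_each = 1 / 64, fg_each = 4 / 64,
                           FG = 2, FGcg = 1 / 16))
    },
    two_cluster_demo = {
      m <- matrix(0L, 8, 8)
      m[2:3, 2:3] <- 1L      # 2x2 grass block, 8 interface pairs
      m[6, 2:4] <- 1L        # 1x3 grass strip, 8 interface pairs
      list(landscape = as_landscape(m),
           expected = list(G = 7 / 64, nc = 2,
                           g = c(4, 3) / 64, fg = c(8, 8) / 64,
                           FG = 16 / 64,
                           FGcg = (4 / 7) * (8 / 64) + (3 / 7) * (8 / 64)))
    },
    block_with_hole_10x10 = {
      m <- matrix(0L, 10, 10)
      m[4:7, 4:7] <- 1L      # 4x4 grass hole, 16 interface pairs
      list(landscape = as_landscape(m),
           expected = list(F = 84 / 100, G = 16 / 100, nc = 1,
                           FG = 16 / 100, FGcg = 16 / 100))
    },
    stop("unknown fixture name: ", name))
}

#' Write run metadata
#'
#' JSON sidecar with the package version, parameters and seed of a run;
#' host-independent fields only, so reruns with identical config and seed
#' are byte-identical.
#'
#' @param path output file.
#' @param params an [fgba_params()] object.
#' @param seed integer seed.
#' @param extra named list of further fields.
#' @export
write_meta <- function(path, params, seed, extra = list()) {
  meta <- c(list(package = "fgba",
                 version = as.character(utils::packageVersion("fgba")),
                 params = unclass(params), seed = seed), extra)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
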