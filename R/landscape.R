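#' @useDynLib fgba, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

.fgba_labels <- c("F", "G", "B", "A")

#' Landscape objects
#'
#' A landscape is a periodic square lattice (torus) whose cells each hold
#' one of the four labels F (forest), G (grass), B (burning), A (ash).
#' Internally it is an integer matrix with codes F=0, G=1, B=2, A=3 and
#' class `fgba_landscape`; adjacency is 4-nearest-neighbour with periodic
#' boundaries in both directions.
#'
#' @param cells an integer matrix of codes 0..3 or a character matrix of
#'   labels in `c("F","G","B","A")`, rows indexing lattice rows.
#' @return An `fgba_landscape` object.
#' @examples
#' ls <- as_landscape(matrix("G", 4, 4))
#' state_fractions(ls)
#' @export
as_landscape <- function(cells) {
  if (is.character(cells)) {
    m <- match(cells, .fgba_labels) - 1L
    if (anyNA(m)) stop("cells must be labels in {F,G,B,A}")
    cells <- matrix(as.integer(m), nrow(cells), ncol(cells))
  }
  if (!is.matrix(cells) || !is.numeric(cells)) {
    stop("cells must be a character or integer matrix")
  }
  storage.mode(cells) <- "integer"
  if (any(is.na(cells)) || any(cells < 0L) || any(cells > 3L)) {
    stop("cell codes must be in 0..3 (F,G,B,A)")
  }
  structure(list(width = ncol(cells), height = nrow(cells),
                 cells = cells, N = length(cells)),
            class = "fgba_landscape")
}

#' Construct an initial landscape
#'
#' Standard initial conditions: `all_grass`, `all_forest`, `uniform_random`
#' (forest placed i.i.d. with probability `f`, grass elsewhere), and
#' `forest_with_hole` (all forest with a centred square hole of grass whose
#' side is rounded so the grass fraction is as close as possible to
#' `hole_fraction`).
#'
#' @param kind one of `"all_grass"`, `"all_forest"`, `"uniform_random"`,
#'   `"forest_with_hole"`.
#' @param width,height lattice dimensions (each at least 2).
#' @param f forest cover fraction for `uniform_random`.
#' @param hole_fraction grass fraction for `forest_with_hole`.
#' @param seed RNG seed (used by `uniform_random` only); the construction
#'   is deterministic given the seed.
#' @return An `fgba_landscape`.
#' @examples
#' initial_landscape("forest_with_hole", 10, 10, hole_fraction = 0.25)
#' @export
initial_landscape <- function(kind = c("all_grass", "all_forest",
                                       "uniform_random", "forest_with_hole"),
                              width, height = width, f = 0.5,
                              hole_fraction = 0.25, seed = 1L) {
  kind <- match.arg(kind)
  if (width < 2 || height < 2) stop("dimensions must be at least 2")
  N <- width * height
  cells <- switch(kind,
    all_grass = matrix(1L, height, width),
    all_forest = matrix(0L, height, width),
    uniform_random = {
      if (f < 0 || f > 1) stop("f must be in [0, 1]")
      set.seed(seed)
      matrix(ifelse(stats::runif(N) < f, 0L, 1L), height, width)
    },
    forest_with_hole = {
      if (hole_fraction < 0 || hole_fraction > 1) {
        stop("hole_fraction must be in [0, 1]")
      }
      side <- round(sqrt(hole_fraction * N))
      side <- min(side, width, height)
      m <- matrix(0L, height, width)
      if (side > 0) {
        r0 <- floor((height - side) / 2) + 1L
        c0 <- floor((width - side) / 2) + 1L
        m[r0:(r0 + side - 1L), c0:(c0 + side - 1L)] <- 1L
      }
      m
    })
  as_landscape(cells)
}

#' @export
print.fgba_landscape <- function(x, ...) {
  fr <- state_fractions(x)
  cat(sprintf("FGBA landscape %d x %d (torus)\n", x$width, x$height))
  cat(sprintf("  [F]=%.4f [G]=%.4f [B]=%.4f [A]=%.4f\n",
              fr["F"], fr["G"], fr["B"], fr["A"]))
  invisible(x)
}

#' @export
plot.fgba_landscape <- function(x, ...) {
  # F dark green, G light, B red, A grey
  cols <- c("#1b5e20", "#e8e3c7", "#d32f2f", "#9e9e9e")
  z <- t(x$cells[x$height:1, , drop = FALSE])
  graphics::image(seq_len(x$width), seq_len(x$height), z,
                  col = cols, zlim = c(-0.5, 3.5), asp = 1,
                  xlab = "", ylab = "", axes = FALSE, ...)
  invisible(x)
}

#' State fractions
#'
#' Fractions of cells in each state, `[x] = (1/N) sum_i delta_x(X_i)`.
#' They sum to one exactly.
#'
#' @param landscape an `fgba_landscape`.
#' @return Named numeric vector with entries `F`, `G`, `B`, `A`.
#' @export
state_fractions <- function(landscape) {
  stopifnot(inherits(landscape, "fgba_landscape"))
  raw_counts(landscape) / landscape$N
}

#' Raw state counts
#'
#' Integer cell counts per state; the integer-exact companion of
#' [state_fractions()].
#' @param landscape an `fgba_landscape`.
#' @return Named integer vector with entries `F`, `G`, `B`, `A`.
#' @export
raw_counts <- function(landscape) {
  stopifnot(inherits(landscape, "fgba_landscape"))
  n <- tabulate(landscape$cells + 1L, nbins = 4L)
  names(n) <- .fgba_labels
  n
}

#' Neighbour-pair density
#'
#' `[xy] = (1/N) sum_{i,j} A_ij delta_x(X_i) delta_y(X_j)` where `A` is the
#' 4-neighbour torus adjacency. For distinct labels each unordered x-y
#' adjacency contributes once; for `x == y` each adjacency contributes
#' twice (both orderings).
#'
#' @param landscape an `fgba_landscape`.
#' @param x,y state labels in `c("F","G","B","A")`.
#' @param raw if `TRUE` return the integer pair count instead of the
#'   N-normalised density.
#' @return A single number.
#' @examples
#' ls <- initial_landscape("all_grass", 4, 4)
#' ls$cells[1, 1] <- 0L  # one forest cell
#' pair_count(ls, "F", "G")  # 4/16
#' @export
pair_count <- function(landscape, x, y, raw = FALSE) {
  stopifnot(inherits(landscape, "fgba_landscape"))
  ix <- match(x, .fgba_labels)
  iy <- match(y, .fgba_labels)
  if (is.na(ix) || is.na(iy)) stop("labels must be in {F,G,B,A}")
  P <- cpp_pair_counts(as.integer(landscape$cells),
                       landscape$width, landscape$height)
  v <- P[ix, iy]
  if (raw) v else v / landscape$N
}

#' Grass-cluster decomposition
#'
#' Maximal 4-connected components of grass cells on the torus. For each
#' cluster `j` the decomposition records its size fraction `[G]_j` and its
#' forest interface `[FG]_j`, the number of forest-grass neighbour pairs
#' between forest and cluster `j` divided by N (a forest cell touching the
#' cluster on two sides contributes 2). Burning and ash cells break grass
#' connectivity. Clusters are numbered in order of first appearance in a
#' row-major scan, so "largest cluster, ties by lowest index" is
#' deterministic.
#'
#' @param landscape an `fgba_landscape`.
#' @return An `fgba_clusters` object: list with `nc`, `g` (`[G]_j`), `fg`
#'   (`[FG]_j`), `sizes` and `fg_pairs` (raw counts), `labels` (matrix of
#'   cluster ids, 0 for non-grass), `landscape`, `N`.
#' @export
grass_clusters <- function(landscape) {
  stopifnot(inherits(landscape, "fgba_landscape"))
  cl <- cpp_grass_clusters(as.integer(landscape$cells),
                           landscape$width, landscape$height)
  N <- landscape$N
  structure(list(nc = length(cl$sizes),
                 g = cl$sizes / N,
                 fg = cl$fg / N,
                 sizes = as.integer(cl$sizes),
                 fg_pairs = as.integer(cl$fg),
                 labels = matrix(cl$labels, landscape$height,
                                 landscape$width),
                 landscape = landscape,
                 N = N),
            class = "fgba_clusters")
}

#' @export
print.fgba_clusters <- function(x, ...) {
  cat(sprintf("grass-cluster decomposition: %d cluster(s), [G]=%.4f, [FG]=%.4f\n",
              x$nc, sum(x$g), sum(x$fg)))
  invisible(x)
}

#' Cluster member indices
#'
#' Linear cell indices (column-major, as in the cells matrix) of the
#' members of grass cluster `j`.
#' @param decomp an `fgba_clusters` object.
#' @param j cluster index.
#' @return Integer vector of cell indices.
#' @export
cluster_members <- function(decomp, j) {
  stopifnot(inherits(decomp, "fgba_clusters"))
  if (j < 1 || j > decomp$nc) stop("invalid cluster index")
  which(decomp$labels == j)
}

#' Grassland-weighted forest perimeter
#'
#' `[FG]cg = sum_j ([G]_j / [G]) [FG]_j`: the forest interface of each
#' grass cluster weighted by the cluster's share of total grass. This is
#' the geometry term governing fire-driven forest loss: a fire ignites in a
#' cluster with probability proportional to its area and erodes that
#' cluster's interface only. Equals `[FG]` when grass forms a single
#' cluster, and is bounded above by `[FG]` in general. Returns 0 when
#' there is no grass.
#'
#' @param decomp an `fgba_clusters` object from [grass_clusters()].
#' @return A single number.
#' @export
weighted_forest_perimeter <- function(decomp) {
  stopifnot(inherits(decomp, "fgba_clusters"))
  if (decomp$nc == 0) return(0)
  G <- sum(decomp$g)
  sum(decomp$g / G * decomp$fg)
}

#' Collapse fast states to vegetation
#'
#' Maps burning and ash cells to grass, giving the slow-timescale
#' vegetation view used by the balance equation (fire converts trees to
#' grass effectively immediately because grass regrowth is much faster
#' than forest dynamics). Set `burning = FALSE` to map only ash.
#'
#' @param landscape an `fgba_landscape`.
#' @param burning also map B cells to G (default `TRUE`).
#' @return An `fgba_landscape` with labels in `{F, G}` only (or `{F,G,B}`
#'   when `burning = FALSE`).
#' @export
vegetation_view <- function(landscape, burning = TRUE) {
  stopifnot(inherits(landscape, "fgba_landscape"))
  cells <- landscape$cells
  cells[cells == 3L] <- 1L
  if (burning) cells[cells == 2L] <- 1L
  as_landscape(cells)
}

#' Read and write landscape grid files
#'
#' Two round-trip-exact on-disk formats. `"text"`: one line per lattice
#' row, characters from `{F,G,B,A}`. `"binary"`: a 12-byte header of three
#' little-endian int32 (width, height, label encoding version = 1L,
#' with codes F=0, G=1, B=2, A=3) followed by one byte per cell in
#' column-major order.
#'
#' @param landscape an `fgba_landscape`.
#' @param path file path.
#' @param format `"text"` or `"binary"`.
#' @return `read_grid` returns an `fgba_landscape`; `write_grid` returns
#'   `path` invisibly.
#' @export
write_grid <- function(landscape, path, format = c("text", "binary")) {
  stopifnot(inherits(landscape, "fgba_landscape"))
  format <- match.arg(format)
  if (format == "text") {
    rows <- apply(landscape$cells, 1, function(r) {
      paste(.fgba_labels[r + 1L], collapse = "")
    })
    writeLines(rows, path)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.integer(c(landscape$width, landscape$height, 1L)), con,
             size = 4L, endian = "little")
    writeBin(as.raw(as.integer(landscape$cells)), con)
  }
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path, format = c("text", "binary")) {
  format <- match.arg(format)
  if (format == "text") {
    rows <- readLines(path)
    rows <- rows[nzchar(rows)]
    chars <- strsplit(rows, "")
    n <- lengths(chars)
    if (length(unique(n)) != 1) stop("ragged grid file")
    m <- matrix(unlist(chars), nrow = length(rows), byrow = TRUE)
    as_landscape(m)
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    hdr <- readBin(con, "integer", 3L, size = 4L, endian = "little")
    if (hdr[3] != 1L) stop("unknown grid encoding version")
    raw <- readBin(con, "raw", hdr[1] * hdr[2])
    as_landscape(matrix(as.integer(raw), hdr[2], hdr[1]))
  }
}
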