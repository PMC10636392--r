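# shared fixtures and independent oracles for the test suite

reference_params <- function(phiN = 0.257, N = 2500, ...) {
  fgba_params(phiN = phiN, N = N, ...)
}

# exact pf = 0.1, pg = 0.9 variant (mu scaled so the ratios are exact)
exact_ratio_params <- function(phiN, N, ...) {
  fgba_params(phiN = phiN, N = N, mu = 9e5, rho_g = 8.1e6, rho_f = 1e5, ...)
}

random_landscape <- function(width, height = width, seed = 1,
                             probs = c(F = 0.4, G = 0.4, B = 0.1, A = 0.1)) {
  set.seed(seed)
  as_landscape(matrix(sample(0:3, width * height, replace = TRUE,
                             prob = probs), height, width))
}

# naive O(N * 4) pair-density oracle, straight from the definition
oracle_pair_count <- function(ls, x, y) {
  lab <- c("F", "G", "B", "A")
  m <- ls$cells
  h <- ls$height
  w <- ls$width
  tot <- 0L
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      if (lab[m[r, c] + 1] != x) next
      nb <- c(m[if (r == 1) h else r - 1, c], m[if (r == h) 1 else r + 1, c],
              m[r, if (c == 1) w else c - 1], m[r, if (c == w) 1 else c + 1])
      tot <- tot + sum(lab[nb + 1] == y)
    }
  }
  tot / ls$N
}

# independent grass-cluster oracle built on igraph components
oracle_grass_clusters <- function(ls) {
  h <- ls$height
  w <- ls$width
  g_idx <- which(ls$cells == 1L)
  if (length(g_idx) == 0) {
    return(list(nc = 0L, sizes = integer(0), fg = integer(0)))
  }
  idx <- function(r, c) (c - 1L) * h + r
  edges <- integer(0)
  for (i in g_idx) {
    r <- (i - 1L) %% h + 1L
    c <- (i - 1L) %/% h + 1L
    for (nb in list(c(if (r == h) 1L else r + 1L, c),
                    c(r, if (c == w) 1L else c + 1L))) {
      j <- idx(nb[1], nb[2])
      if (ls$cells[j] == 1L) edges <- c(edges, i, j)
    }
  }
  g <- igraph::graph_from_edgelist(matrix(match(edges, g_idx), ncol = 2,
                                          byrow = TRUE), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(g_idx) - igraph::vcount(g)))
  comp <- igraph::components(g)
  # forest-neighbour slots per grass cell
  fexp <- vapply(g_idx, function(i) {
    r <- (i - 1L) %% h + 1L
    c <- (i - 1L) %/% h + 1L
    nb <- c(idx(if (r == 1) h else r - 1L, c), idx(if (r == h) 1L else r + 1L, c),
            idx(r, if (c == 1) w else c - 1L), idx(r, if (c == w) 1L else c + 1L))
    sum(ls$cells[nb] == 0L)
  }, numeric(1))
  sizes <- as.integer(table(comp$membership))
  fg <- as.integer(tapply(fexp, comp$membership, sum))
  list(nc = comp$no, sizes = sizes, fg = fg)
}

# brute-force stationary distribution of the 2x2 CTMC (256 states); state
# code matches the engine's occupancy coding (column-major, base 4)
oracle_stationary_2x2 <- function(p) {
  nb <- list(c(2, 2, 3, 3), c(1, 1, 4, 4), c(4, 4, 1, 1), c(3, 3, 2, 2))
  dec <- function(code) {
    s <- integer(4)
    for (i in 1:4) {
      s[i] <- code %% 4
      code <- code %/% 4
    }
    s
  }
  enc <- function(s) sum(s * 4^(0:3))
  Q <- matrix(0, 256, 256)
  for (c0 in 0:255) {
    s <- dec(c0)
    for (i in 1:4) {
      nF <- sum(s[nb[[i]]] == 0)
      nB <- sum(s[nb[[i]]] == 2)
      trs <- switch(s[i] + 1,
        list(c(1, p$gamma), c(2, p$rho_f * nB)),
        list(c(0, p$beta + p$alpha * nF), c(2, p$phi + p$rho_g * nB)),
        list(c(3, p$mu)),
        list(c(0, p$beta + p$alpha * nF), c(1, p$lambda)))
      for (tr in trs) {
        if (tr[2] > 0) {
          s2 <- s
          s2[i] <- tr[1]
          Q[c0 + 1, enc(s2) + 1] <- Q[c0 + 1, enc(s2) + 1] + tr[2]
        }
      }
    }
  }
  diag(Q) <- -rowSums(Q)
  pi <- qr.solve(rbind(t(Q), rep(1, 256)), c(rep(0, 256), 1))
  names(pi) <- as.character(0:255)
  pi
}

# empirical occupancy distribution of a trajectory, aligned to 0:255
occupancy_distribution_2x2 <- function(tr) {
  emp <- stats::setNames(rep(0, 256), as.character(0:255))
  occ <- tr$occupancy / sum(tr$occupancy)
  emp[names(occ)] <- occ
  emp
}
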