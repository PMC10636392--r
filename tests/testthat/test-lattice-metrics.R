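test_that("state fractions match direct counting", {
  expect_equal(state_fractions(initial_landscape("all_grass", 10, 10)),
               c(F = 0, G = 1, B = 0, A = 0))
  ls <- initial_landscape("all_grass", 4, 4)
  ls$cells[2, 2] <- 0L
  expect_equal(state_fractions(ls)[["F"]], 1 / 16)
  # independent full-scan recount on a random landscape
  ls <- random_landscape(100, seed = 11)
  naive <- table(factor(c("F", "G", "B", "A")[ls$cells + 1],
                        levels = c("F", "G", "B", "A"))) / ls$N
  expect_equal(unname(state_fractions(ls)), as.numeric(naive))
  expect_equal(sum(state_fractions(ls)), 1)
  expect_equal(sum(raw_counts(ls)), ls$N)
})

test_that("pair densities follow the adjacency-sum definition", {
  expect_equal(pair_count(initial_landscape("all_forest", 8, 8), "F", "G"), 0)
  ls <- initial_landscape("all_grass", 4, 4)
  ls$cells[2, 2] <- 0L
  expect_equal(pair_count(ls, "F", "G"), 4 / 16)
  expect_error(pair_count(ls, "F", "X"), "labels")
  # symmetry and agreement with the naive oracle on random landscapes
  for (seed in 1:3) {
    ls <- random_landscape(20, seed = seed)
    for (pair in list(c("F", "G"), c("G", "B"), c("F", "A"))) {
      v <- pair_count(ls, pair[1], pair[2])
      expect_equal(v, pair_count(ls, pair[2], pair[1]))
      expect_equal(v, oracle_pair_count(ls, pair[1], pair[2]))
    }
  }
})

test_that("mean F-G pair density on uncorrelated landscapes is 4f(1-f)", {
  for (f in seq(0.1, 0.9, by = 0.1)) {
    vals <- vapply(1:25, function(s) {
      ls <- initial_landscape("uniform_random", 100, 100, f = f,
                             seed = 1000 * f + s)
      pair_count(ls, "F", "G")
    }, numeric(1))
    se <- stats::sd(vals) / sqrt(length(vals))
    expect_lt(abs(mean(vals) - 4 * f * (1 - f)), 3 * se + 1e-9)
  }
})

test_that("grass clusters are maximal 4-connected components on the torus", {
  d <- grass_clusters(initial_landscape("all_grass", 6, 6))
  expect_equal(d$nc, 1)
  expect_equal(d$g, 1)
  expect_equal(d$fg, 0)
  # checkerboard isolates every grass cell under 4-connectivity
  cb <- make_fixture("checkerboard_8x8")
  d <- grass_clusters(cb$landscape)
  expect_equal(d$nc, cb$expected$nc)
  expect_true(all(d$g == cb$expected$g_each))
  expect_true(all(d$fg == cb$expected$fg_each))
  # rectangular hole: hand-counted boundary pairs
  bh <- make_fixture("block_with_hole_10x10")
  d <- grass_clusters(bh$landscape)
  expect_equal(d$nc, 1)
  expect_equal(d$fg, bh$expected$FG)
  # wrap-around: a grass column touching both vertical edges is one cluster
  m <- matrix(0L, 6, 6)
  m[, 1] <- 1L
  expect_equal(grass_clusters(as_landscape(m))$nc, 1)
})

test_that("cluster decomposition agrees with an independent igraph oracle", {
  skip_if_not_installed("igraph")
  for (seed in 1:4) {
    ls <- random_landscape(15, seed = seed,
                           probs = c(F = 0.45, G = 0.45, B = 0.05, A = 0.05))
    d <- grass_clusters(ls)
    o <- oracle_grass_clusters(ls)
    expect_equal(d$nc, o$nc)
    expect_equal(sort(d$sizes), sort(o$sizes))
    expect_equal(sort(d$fg_pairs), sort(o$fg))
    # decomposition sums reproduce the global quantities exactly
    expect_equal(sum(d$g), state_fractions(ls)[["G"]])
    expect_equal(sum(d$fg), pair_count(ls, "F", "G"))
  }
})

test_that("weighted perimeter combines clusters by relative grass share", {
  # direct substitution: g = (0.3, 0.1), fg = (0.2, 0.05)
  d <- structure(list(nc = 2L, g = c(0.3, 0.1), fg = c(0.2, 0.05)),
                 class = "fgba_clusters")
  expect_equal(weighted_forest_perimeter(d), 0.1625)
  # single cluster: weighted perimeter equals the plain pair density
  bh <- make_fixture("block_with_hole_10x10")$landscape
  expect_equal(weighted_forest_perimeter(grass_clusters(bh)),
               pair_count(bh, "F", "G"))
  # no grass: 0 by convention
  expect_equal(weighted_forest_perimeter(
    grass_clusters(initial_landscape("all_forest", 5, 5))), 0)
  # always bounded by the plain pair density; strict for multi-cluster
  tc <- make_fixture("two_cluster_demo")
  dd <- grass_clusters(tc$landscape)
  expect_equal(weighted_forest_perimeter(dd), tc$expected$FGcg)
  expect_lt(weighted_forest_perimeter(dd), pair_count(tc$landscape, "F", "G"))
  for (seed in 5:8) {
    ls <- random_landscape(20, seed = seed)
    expect_lte(weighted_forest_perimeter(grass_clusters(ls)),
               pair_count(ls, "F", "G") + 1e-12)
  }
})

test_that("cluster member lists partition the grass cells", {
  tc <- make_fixture("two_cluster_demo")$landscape
  d <- grass_clusters(tc)
  mem <- lapply(seq_len(d$nc), cluster_members, decomp = d)
  expect_equal(sort(unlist(mem)), which(tc$cells == 1L))
  expect_equal(lengths(mem), d$sizes)
  expect_error(cluster_members(d, 99), "invalid")
})

test_that("vegetation view maps fast states to grass", {
  ls <- random_landscape(10, seed = 3)
  v <- vegetation_view(ls)
  expect_true(all(v$cells %in% c(0L, 1L)))
  expect_equal(state_fractions(v)[["F"]], state_fractions(ls)[["F"]])
  v2 <- vegetation_view(ls, burning = FALSE)
  expect_equal(sum(v2$cells == 2L), sum(ls$cells == 2L))
  expect_equal(sum(v2$cells == 3L), 0L)
})

test_that("grid files round-trip bit-exactly in both formats", {
  ls <- random_landscape(9, 13, seed = 5)
  for (fmt in c("text", "binary")) {
    path <- tempfile(fileext = if (fmt == "text") ".grid" else ".bin")
    write_grid(ls, path, format = fmt)
    back <- read_grid(path, format = fmt)
    expect_identical(back$cells, ls$cells)
    expect_equal(back$width, ls$width)
    expect_equal(back$height, ls$height)
    unlink(path)
  }
})

test_that("landscape constructors honour their contracts", {
  expect_equal(state_fractions(initial_landscape("all_grass", 10))[["G"]], 1)
  expect_equal(state_fractions(
    initial_landscape("forest_with_hole", 100, 100,
                      hole_fraction = 0.25))[["G"]], 0.25)
  ls <- initial_landscape("uniform_random", 100, 100, f = 0.5, seed = 2)
  se <- sqrt(0.5 * 0.5 / 1e4)
  expect_lt(abs(state_fractions(ls)[["F"]] - 0.5), 3 * se)
  # deterministic given seed
  ls2 <- initial_landscape("uniform_random", 100, 100, f = 0.5, seed = 2)
  expect_identical(ls$cells, ls2$cells)
  expect_error(initial_landscape("uniform_random", 10, f = 1.5), "\\[0, 1\\]")
  expect_error(initial_landscape("all_grass", 1, 5), "at least 2")
  expect_error(as_landscape(matrix(c("F", "Q"), 1, 2)), "labels")
})
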