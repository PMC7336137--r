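tri_graph <- function(w12 = 1, w23 = 1, w13 = 1) {
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- w12
  m[2, 3] <- m[3, 2] <- w23
  m[1, 3] <- m[3, 1] <- w13
  proportional_threshold(m, 1)
}

test_that("quadrant extraction slices the intra-hemispheric blocks", {
  atlas <- default_atlas()
  blocks <- hemisphere_blocks(atlas)
  adj <- matrix(9, 246, 246)
  adj[blocks$left, blocks$left] <- 1
  adj[blocks$right, blocks$right] <- 2
  diag(adj) <- 0
  expect_true(all(extract_quadrant(adj, atlas, "left")[
    upper.tri(diag(123))] == 1))
  expect_true(all(extract_quadrant(adj, atlas, "right")[
    upper.tri(diag(123))] == 2))

  r <- rand_adjacency(246, seed = 2)
  expect_equal(extract_quadrant(r, atlas, "right"),
               r[blocks$right, blocks$right])
  expect_equal(extract_quadrant(r, atlas, "left"),
               t(extract_quadrant(r, atlas, "left")))
  expect_error(extract_quadrant(r[1:10, 1:10], atlas, "left"), "246")
})

test_that("proportional thresholding keeps the strongest edges", {
  # N = 5 at 10%: round(0.1 * 10) = 1 edge
  m <- rand_adjacency(5, density = 1, seed = 3)
  g <- proportional_threshold(m, 0.10)
  expect_equal(g$n_edges, 1)
  expect_equal(max(g$weights), max(m))

  # all-equal weights: ties resolved lexicographically by (i, j)
  eq <- matrix(1, 4, 4)
  diag(eq) <- 0
  g_eq <- proportional_threshold(eq, 0.5)  # 3 of 6 edges
  kept <- which(g_eq$weights > 0 & upper.tri(g_eq$weights), arr.ind = TRUE)
  kept <- kept[order(kept[, 2], kept[, 1]), ]
  expect_equal(unname(kept), rbind(c(1, 2), c(1, 3), c(1, 4)))

  # random 20-node matrix: retained set equals the sort-based brute force
  m20 <- rand_adjacency(20, density = 1, seed = 4)
  g20 <- proportional_threshold(m20, 0.10)
  n_keep <- round(0.10 * 20 * 19 / 2)
  ut <- which(upper.tri(m20))
  expected_kept <- ut[order(-m20[ut])][seq_len(n_keep)]
  got_kept <- which(g20$weights > 0 & upper.tri(m20))
  expect_setequal(got_kept, expected_kept)
  expect_equal(g20$weights[got_kept], m20[got_kept])
  expect_equal(g20$lengths[got_kept], 1 / m20[got_kept])

  expect_error(proportional_threshold(m20, 0), "density")
  expect_error(proportional_threshold(m20, 1.2), "density")

  # absolute mode keeps weights strictly above the cutoff
  g_abs <- proportional_threshold(m20, method = "absolute", cutoff = 0.8)
  expect_true(all(g_abs$weights[g_abs$weights > 0] > 0.8))
})

test_that("shortest paths match Floyd-Warshall on random graphs", {
  for (s in 1:5) {
    g <- proportional_threshold(rand_adjacency(30, 0.3, seed = 10 + s), 1)
    d <- shortest_path_lengths(g)
    expect_equal(d, unname(bf_floyd_warshall(g$lengths)),
                 tolerance = 1e-12)
  }
})

test_that("global measures reproduce the hand-computed fixtures", {
  gm_tri <- global_measures(tri_graph())
  expect_equal(gm_tri$ge, 1)
  expect_equal(gm_tri$cpl, 1)
  expect_equal(gm_tri$transitivity, 1)

  gm_path <- global_measures(tri_graph(w13 = 0))
  expect_equal(gm_path$cpl, 4 / 3)
  expect_equal(gm_path$ge, 5 / 6)
  expect_equal(gm_path$transitivity, 0)

  # two disconnected dyads: CPL over connected pairs only, GE counts zeros
  dy <- matrix(0, 4, 4)
  dy[1, 2] <- dy[2, 1] <- dy[3, 4] <- dy[4, 3] <- 1
  gm_dy <- global_measures(proportional_threshold(dy, 1))
  expect_equal(gm_dy$cpl, 1)
  expect_equal(gm_dy$ge, 1 / 3)

  # weighted triangle: T = CC = (w12 w23 w13)^(1/3) / max-normalized
  gm_w <- global_measures(tri_graph(1, 1, 0.5))
  expect_equal(gm_w$transitivity, 0.5^(1 / 3))

  empty <- proportional_threshold(matrix(0, 3, 3), 1)
  expect_warning(gm_e <- global_measures(empty), "CPL")
  expect_equal(gm_e$ge, 0)
  expect_true(is.nan(gm_e$cpl))
})

test_that("nodal measures reproduce the hand-computed fixtures", {
  nm_tri <- nodal_measures(tri_graph())
  expect_equal(nm_tri$cc, rep(1, 3))
  expect_equal(nm_tri$ne, rep(1, 3))
  expect_equal(nm_tri$bc, rep(0, 3))
  expect_equal(nm_tri$evc, rep(1 / sqrt(3), 3))

  nm_path <- nodal_measures(tri_graph(w13 = 0))
  expect_equal(nm_path$bc[2], 0.5)
  expect_equal(nm_path$bc[c(1, 3)], c(0, 0))
  expect_equal(nm_path$ne, c(0.75, 1, 0.75))
  expect_equal(nm_path$evc, c(0.5, sqrt(0.5), 0.5), tolerance = 1e-10)

  nm_w <- nodal_measures(tri_graph(1, 1, 0.5))
  expect_equal(nm_w$cc, rep(0.5^(1 / 3), 3))

  # raw betweenness counts via the flag
  expect_equal(nodal_measures(tri_graph(w13 = 0), bc_raw = TRUE)$bc[2], 1)
})

test_that("all measures agree with brute force on random small graphs", {
  for (s in 1:25) {
    set.seed(500 + s)
    n <- sample(5:12, 1)
    dens <- runif(1, 0.2, 0.8)
    g <- proportional_threshold(rand_adjacency(n, dens), 1)
    gm <- global_measures(g)
    bf_g <- bf_global_measures(g$weights)
    expect_equal(gm$ge, bf_g$ge, tolerance = 1e-9)
    if (!is.nan(gm$cpl)) expect_equal(gm$cpl, bf_g$cpl, tolerance = 1e-9)
    expect_equal(gm$transitivity, bf_g$transitivity, tolerance = 1e-9)
    nm <- nodal_measures(g)
    bf_n <- bf_nodal_measures(g$weights)
    expect_equal(nm$cc, bf_n$cc, tolerance = 1e-9)
    expect_equal(nm$ne, bf_n$ne, tolerance = 1e-9)
    expect_equal(nm$bc, bf_n$bc, tolerance = 1e-9)
    expect_equal(nm$evc, bf_n$evc, tolerance = 1e-8)
  }
})

test_that("transitivity is not the mean clustering coefficient", {
  # ring lattice (regular): T equals mean CC
  n <- 8
  ring <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (d in 1:2) {
      j <- ((i + d - 1) %% n) + 1
      ring[i, j] <- ring[j, i] <- 1
    }
  }
  g_ring <- proportional_threshold(ring, 1)
  expect_equal(global_measures(g_ring)$transitivity,
               mean(nodal_measures(g_ring)$cc), tolerance = 1e-12)

  # heterogeneous-degree graph: they differ
  set.seed(99)
  g_rand <- proportional_threshold(rand_adjacency(10, 0.4), 1)
  t_val <- global_measures(g_rand)$transitivity
  cc_mean <- mean(nodal_measures(g_rand)$cc)
  expect_gt(abs(t_val - cc_mean), 1e-3)
})

test_that("uniform-weight graphs scale like their binary counterparts", {
  set.seed(7)
  mask <- rand_adjacency(9, 0.5) > 0
  for (w in c(0.5, 2)) {
    m <- matrix(0, 9, 9)
    m[mask] <- w
    g_w <- global_measures(proportional_threshold(m, 1))
    m1 <- matrix(0, 9, 9)
    m1[mask] <- 1
    g_1 <- global_measures(proportional_threshold(m1, 1))
    expect_equal(g_w$ge, w * g_1$ge, tolerance = 1e-12)
    expect_equal(g_w$cpl, g_1$cpl / w, tolerance = 1e-12)
    expect_equal(g_w$transitivity, g_1$transitivity, tolerance = 1e-12)
  }
})
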