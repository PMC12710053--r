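test_that("thinning leaves thin structures, empties, and is a fixed point", {
  line <- matrix(FALSE, 3, 7); line[2, 2:6] <- TRUE
  expect_identical(thin_mask(line), line)
  expect_identical(thin_mask(matrix(FALSE, 4, 4)), matrix(FALSE, 4, 4))

  rect <- matrix(FALSE, 10, 24); rect[3:8, 3:22] <- TRUE
  sk <- thin_mask(rect)
  expect_true(all(!(sk & !rect)))            # subset of input
  expect_identical(thin_mask(sk), sk)        # idempotent
  # 8-connectivity by flood fill oracle from one skeleton pixel
  g <- build_skeleton_graph(sk)
  expect_equal(igraph::components(g$graph)$no, 1)
})

test_that("skeleton graphs follow the 8-neighbourhood with stated weights", {
  line3 <- mask_from_xy(rbind(c(1, 1), c(2, 1), c(3, 1)), 3, 5)
  g <- build_skeleton_graph(line3)
  expect_equal(nrow(g$coords), 3)
  expect_equal(igraph::ecount(g$graph), 2)
  expect_true(all(igraph::E(g$graph)$weight == 1))

  diag2 <- mask_from_xy(rbind(c(0, 0), c(1, 1)), 3, 3)
  g <- build_skeleton_graph(diag2)
  expect_equal(igraph::ecount(g$graph), 1)
  expect_equal(igraph::E(g$graph)$weight, 2)

  # brute-force adjacency oracle on random sparse rasters
  set.seed(53)
  for (i in 1:5) {
    m <- random_sparse_mask(12, 12, 0.2)
    g <- build_skeleton_graph(m, 2)
    pts <- g$coords
    n <- nrow(pts)
    adj_oracle <- 0L
    if (n > 1) for (a in 1:(n - 1)) for (b in (a + 1):n) {
      dx <- abs(pts[a, 1] - pts[b, 1]); dy <- abs(pts[a, 2] - pts[b, 2])
      if (max(dx, dy) == 1) adj_oracle <- adj_oracle + 1L
    }
    expect_equal(igraph::ecount(g$graph), adj_oracle)
  }
})

test_that("endpoints and intersections are the degree-1 and degree>=3 vertices", {
  line3 <- mask_from_xy(rbind(c(1, 1), c(2, 1), c(3, 1)), 3, 5)
  g <- build_skeleton_graph(line3)
  ep <- skeleton_endpoints(g)
  expect_equal(nrow(ep), 2)
  expect_equal(nrow(skeleton_intersections(g)), 0)

  xpts <- rbind(c(0, 0), c(1, 1), c(2, 2), c(3, 3), c(4, 4),
                c(0, 4), c(1, 3), c(3, 1), c(4, 0))
  g <- build_skeleton_graph(mask_from_xy(xpts, 5, 5))
  ep <- skeleton_endpoints(g)
  expect_equal(nrow(ep), 4)
  expect_setequal(paste(ep[, 1], ep[, 2]), c("0 0", "4 0", "0 4", "4 4"))
  it <- skeleton_intersections(g)
  expect_equal(unname(it[1, ]), c(2, 2))
  expect_equal(igraph::degree(g$graph)[radlen:::graph_vertex_id(g, c(2, 2))],
               4, ignore_attr = TRUE)

  # degree oracle on random masks
  set.seed(59)
  m <- random_sparse_mask(15, 15, 0.18)
  g <- build_skeleton_graph(m)
  pts <- g$coords
  deg_oracle <- vapply(seq_len(nrow(pts)), function(a) {
    sum(vapply(seq_len(nrow(pts)), function(b) {
      a != b && max(abs(pts[a, ] - pts[b, ])) == 1
    }, logical(1)))
  }, numeric(1))
  expect_setequal(paste(skeleton_endpoints(g)[, 1], skeleton_endpoints(g)[, 2]),
                  paste(pts[deg_oracle == 1, 1], pts[deg_oracle == 1, 2]))
  expect_setequal(paste(skeleton_intersections(g)[, 1], skeleton_intersections(g)[, 2]),
                  paste(pts[deg_oracle >= 3, 1], pts[deg_oracle >= 3, 2]))
})

test_that("vertex-to-graph distance is the exhaustive Euclidean minimum", {
  g1 <- build_skeleton_graph(mask_from_xy(rbind(c(3, 4)), 6, 6))
  expect_equal(vertex_graph_distance(c(0, 0), g1), 5)
  expect_equal(vertex_graph_distance(c(3, 4), g1), 0)

  set.seed(61)
  m <- random_sparse_mask(20, 20, 0.5)
  g <- build_skeleton_graph(m)
  v <- c(7, 13)
  oracle <- min(sqrt((g$coords[, 1] - v[1])^2 + (g$coords[, 2] - v[2])^2))
  expect_equal(vertex_graph_distance(v, g), oracle)
})

test_that("geodesic distances match an independent Bellman-Ford oracle", {
  line5 <- mask_from_xy(cbind(1:5, 2), 5, 7)
  g <- build_skeleton_graph(line5)
  expect_equal(geodesic_distance(g, c(1, 2), c(1, 2)), 0)
  expect_equal(geodesic_distance(g, c(1, 2), c(5, 2)), 4)

  diag5 <- mask_from_xy(cbind(0:4, 0:4), 5, 5)
  g <- build_skeleton_graph(diag5, 2)
  expect_equal(geodesic_distance(g, c(0, 0), c(4, 4)), 8)
  g <- build_skeleton_graph(diag5, sqrt(2))
  expect_equal(geodesic_distance(g, c(0, 0), c(4, 4)), 4 * sqrt(2))

  # disconnected components error
  two <- mask_from_xy(rbind(c(0, 0), c(4, 4)), 5, 5)
  g <- build_skeleton_graph(two)
  expect_error(geodesic_distance(g, c(0, 0), c(4, 4)), "disconnected")

  set.seed(67)
  for (w in c(2, sqrt(2))) {
    for (i in 1:10) {
      m <- random_sparse_mask(15, 15, 0.35)
      g <- build_skeleton_graph(m, w)
      n <- nrow(g$coords)
      src <- ((i * 7) %% n) + 1
      d_oracle <- bellman_ford_oracle(g, src)
      d_pkg <- igraph::distances(g$graph, v = src, algorithm = "dijkstra")[1, ]
      expect_equal(unname(d_pkg), d_oracle, tolerance = 1e-10)
    }
  }
})

test_that("geodesics are symmetric, metric, and count steps by weight class", {
  set.seed(71)
  m <- random_sparse_mask(14, 14, 0.4)
  g <- build_skeleton_graph(m, 2)
  comp <- igraph::components(g$graph)
  big <- which(comp$membership == which.max(comp$csize))
  ids <- head(big, 5)
  D <- igraph::distances(g$graph, v = ids, to = ids, algorithm = "dijkstra")
  expect_equal(D, t(D))
  for (a in 1:5) for (b in 1:5) for (cc in 1:5)
    expect_lte(D[a, b], D[a, cc] + D[cc, b] + 1e-9)

  # on any shortest path, weight = #orthogonal + 2 * #diagonal steps
  p <- igraph::shortest_paths(g$graph, from = ids[1], to = ids[min(5, length(ids))],
                              weights = igraph::E(g$graph)$weight)$vpath[[1]]
  pts <- g$coords[as.integer(p), , drop = FALSE]
  if (nrow(pts) > 1) {
    steps <- abs(diff(pts))
    n_diag <- sum(steps[, 1] & steps[, 2])
    n_orth <- nrow(steps) - n_diag
    expect_equal(geodesic_distance(g, pts[1, ], pts[nrow(pts), ]),
                 n_orth + 2 * n_diag)
  }
})

test_that("the disk-with-bar fixture measures the bar length via the fallback", {
  fx <- disk_with_bar(radius = 8, bar_len = 41)
  m <- radicle_pixel_length(fx$coat, fx$radicle, 2)
  expect_true("no_intersection_fallback" %in% m$flags)
  expect_lt(abs(m$pixel_length - 40), 2 + 1e-9)

  # empty radicle degenerates cleanly
  m0 <- radicle_pixel_length(fx$coat, fx$radicle & FALSE, 2)
  expect_equal(m0$pixel_length, 0)
  expect_equal(m0$flags, "no_radicle")
  expect_error(radicle_pixel_length(fx$coat & FALSE, fx$radicle), "coat")
})

test_that("a branched radicle follows the farthest-endpoint / nearest-junction rule", {
  # coat bar on the left; radicle: horizontal spine with a short side branch
  coat <- mask_from_xy(cbind(0:3, 10), 21, 40)
  spine <- cbind(5:30, 10)
  branch <- cbind(12, 11:16)
  rad <- mask_from_xy(rbind(spine, branch), 21, 40)
  m <- radicle_pixel_length(coat, rad, 2)

  # exhaustive-candidate oracle under the same selection rule
  g_s <- build_skeleton_graph(thin_mask(coat), 2)
  g_r <- build_skeleton_graph(thin_mask(rad), 2)
  deg <- igraph::degree(g_r$graph)
  dmin <- vapply(seq_len(nrow(g_r$coords)), function(i)
    vertex_graph_distance(g_r$coords[i, ], g_s), numeric(1))
  eps <- which(deg == 1)
  p_e <- g_r$coords[eps[which.max(dmin[eps])], ]
  ints <- which(deg >= 3)
  p_i <- g_r$coords[ints[which.min(dmin[ints])], ]
  expect_equal(m$p_e, unname(p_e))
  expect_equal(m$p_i, unname(p_i))
  expect_equal(m$pixel_length, geodesic_distance(g_r, p_e, p_i))
  expect_false("no_intersection_fallback" %in% m$flags)
})

test_that("pixel length is invariant under translation and 90-degree rotation", {
  fx <- disk_with_bar(radius = 7, bar_len = 31, rows = 50, cols = 90)
  base <- radicle_pixel_length(fx$coat, fx$radicle, 2)$pixel_length

  shift_mask <- function(m, dr, dc) {
    out <- matrix(FALSE, nrow(m), ncol(m))
    idx <- which(m, arr.ind = TRUE)
    out[cbind(idx[, 1] + dr, idx[, 2] + dc)] <- TRUE
    out
  }
  tr <- radicle_pixel_length(shift_mask(fx$coat, 3, 2),
                             shift_mask(fx$radicle, 3, 2), 2)$pixel_length
  expect_equal(tr, base)

  rot <- function(m) t(m)[ncol(m):1, , drop = FALSE]
  ro <- radicle_pixel_length(rot(fx$coat), rot(fx$radicle), 2)$pixel_length
  expect_equal(ro, base)
})

test_that("known radicle lengths are recovered from generator ground truth", {
  errs <- c()
  for (sd in 101:117) {
    scene <- generate_scene(scene_params(rng_seed = sd))
    for (s in scene$seeds) {
      m <- radicle_pixel_length(s$coat, s$radicle, 2)
      errs <- c(errs, abs(m$pixel_length - s$arc_length_px))
    }
  }
  expect_gte(length(errs), 40)
  expect_lte(mean(errs), 2)
})
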