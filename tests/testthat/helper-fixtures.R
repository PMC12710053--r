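# Shared fixtures, built in code.

# Uniform-colour image.
flat_image <- function(rgb, rows = 10, cols = 10) {
  px <- array(0L, c(rows, cols, 3))
  for (ch in 1:3) px[, , ch] <- as.integer(rgb[ch])
  seed_image(px, image_id = "flat")
}

# Logical mask from a list/matrix of 0-based (x, y) pixels.
mask_from_xy <- function(pts, rows, cols) {
  m <- matrix(FALSE, rows, cols)
  pts <- if (is.list(pts)) do.call(rbind, pts) else pts
  m[cbind(pts[, 2] + 1L, pts[, 1] + 1L)] <- TRUE
  m
}

# Random sparse skeleton-like raster with a fixed fill fraction.
random_sparse_mask <- function(rows, cols, fill = 0.15) {
  matrix(runif(rows * cols) < fill, rows, cols)
}

# Disk coat with an attached 1-px horizontal bar radicle (the canonical
# unbranched fixture): bar starts 1 px inside the disk and extends
# `bar_len` pixels in total.
disk_with_bar <- function(radius = 8, bar_len = 41, rows = 40, cols = 80) {
  cy <- 20; cx <- 20
  g <- as.matrix(expand.grid(r = 1:rows, c = 1:cols))
  disk <- matrix((g[, "r"] - cy)^2 + (g[, "c"] - cx)^2 <= radius^2, rows, cols)
  bar <- matrix(FALSE, rows, cols)
  x0 <- cx + radius          # 1-based col of the boundary pixel
  bar[cy, x0:(x0 + bar_len - 1)] <- TRUE
  list(coat = disk & !bar, radicle = bar)
}

# Independent Bellman-Ford shortest path oracle over a skeleton_graph.
bellman_ford_oracle <- function(graph, src_id) {
  n <- nrow(graph$coords)
  el <- igraph::as_edgelist(graph$graph, names = FALSE)
  w <- igraph::E(graph$graph)$weight
  dist <- rep(Inf, n)
  dist[src_id] <- 0
  for (iter in seq_len(n)) {
    nd <- pmin(dist,
               pmin(tapply_min(el[, 2], dist[el[, 1]] + w, n),
                    tapply_min(el[, 1], dist[el[, 2]] + w, n)))
    if (isTRUE(all.equal(nd, dist))) break
    dist <- nd
  }
  dist
}

tapply_min <- function(idx, val, n) {
  out <- rep(Inf, n)
  if (length(idx)) {
    o <- order(val, decreasing = TRUE)
    out[idx[o]] <- val[o]   # last write wins = smallest value
  }
  out
}
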