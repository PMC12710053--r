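# Skeletonization and skeleton-graph metrology: Zhang-Suen thinning, a
# weighted 8-neighbourhood graph over skeleton pixels, endpoint/junction
# detection, geodesic distances, and the radicle pixel-length measurement.

#' Zhang-Suen thinning
#'
#' Iterative two-subiteration thinning of a binary mask down to a one-pixel
#' wide skeleton; iterates until no pixel changes.  The skeleton is always a
#' subset of the input and re-thinning it is a fixed point.
#'
#' @param mask Logical matrix.
#' @return Logical matrix of skeleton pixels.
#' @export
thin_mask <- function(mask) {
  stopifnot(is.matrix(mask))
  m <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  if (!any(m == 1L)) return(mask & FALSE)
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      # neighbours P2..P9 clockwise from north
      p2 <- shift_mat(m,  1L,  0L); p3 <- shift_mat(m,  1L, -1L)
      p4 <- shift_mat(m,  0L, -1L); p5 <- shift_mat(m, -1L, -1L)
      p6 <- shift_mat(m, -1L,  0L); p7 <- shift_mat(m, -1L,  1L)
      p8 <- shift_mat(m,  0L,  1L); p9 <- shift_mat(m,  1L,  1L)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0L & p3 == 1L) + (p3 == 0L & p4 == 1L) +
           (p4 == 0L & p5 == 1L) + (p5 == 0L & p6 == 1L) +
           (p6 == 0L & p7 == 1L) + (p7 == 0L & p8 == 1L) +
           (p8 == 0L & p9 == 1L) + (p9 == 0L & p2 == 1L)
      if (sub == 1L) {
        cond <- p2 * p4 * p6 == 0L & p4 * p6 * p8 == 0L
      } else {
        cond <- p2 * p4 * p8 == 0L & p2 * p6 * p8 == 0L
      }
      del <- m == 1L & b >= 2L & b <= 6L & a == 1L & cond
      if (any(del)) { m[del] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  m == 1L
}

# Note on orientation: shift_mat(m, 1, 0) places each pixel's value one row
# down, i.e. the matrix read at (r, c) is the original (r-1, c) — the
# northern neighbour when rows grow downward.  The labelling of P2..P9 only
# needs to be a consistent clockwise cycle for Zhang-Suen, which it is.

#' Build the weighted skeleton graph
#'
#' One vertex per skeleton pixel; an edge joins every pair of 8-neighbours.
#' Orthogonal (horizontal/vertical) edges weigh 1; diagonal edges weigh
#' `diagonal_weight` (default 2, the Manhattan-like convention; use
#' `sqrt(2)` for Euclidean polyline lengths).
#'
#' @param skeleton Logical matrix of skeleton pixels.
#' @param diagonal_weight Positive diagonal edge weight.
#' @return A `skeleton_graph`: list with `coords` (n x 2 matrix of 0-based
#'   `(x, y)` pixel coordinates), `graph` (igraph), `diagonal_weight`.
#' @export
build_skeleton_graph <- function(skeleton, diagonal_weight = 2) {
  stopifnot(is.matrix(skeleton), diagonal_weight > 0)
  idx <- which(skeleton, arr.ind = TRUE)  # 1-based (row, col)
  n <- nrow(idx)
  coords <- cbind(x = idx[, 2] - 1L, y = idx[, 1] - 1L)
  nr <- nrow(skeleton)
  key <- (idx[, 2] - 1L) * nr + idx[, 1]       # linear index of each vertex
  vid <- integer(nr * ncol(skeleton))
  vid[key] <- seq_len(n)
  edges <- NULL; weights <- NULL
  if (n > 0L) {
    # scan four directions (E, S, SE, NE); undirected graph so this covers
    # all 8-neighbour pairs exactly once
    dirs <- list(c(0L, 1L, 1), c(1L, 0L, 1),
                 c(1L, 1L, diagonal_weight), c(-1L, 1L, diagonal_weight))
    ee <- list(); ww <- list()
    for (d in dirs) {
      rr <- idx[, 1] + d[1]; cc <- idx[, 2] + d[2]
      ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= ncol(skeleton)
      ok[ok] <- skeleton[cbind(rr[ok], cc[ok])]
      if (any(ok)) {
        from <- which(ok)
        to <- vid[(cc[ok] - 1L) * nr + rr[ok]]
        ee[[length(ee) + 1L]] <- rbind(from, to)
        ww[[length(ww) + 1L]] <- rep(d[3], length(from))
      }
    }
    if (length(ee)) {
      edges <- do.call(cbind, ee)
      weights <- unlist(ww)
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (!is.null(edges))
    g <- igraph::add_edges(g, as.vector(edges), weight = weights)
  structure(list(coords = coords, graph = g,
                 diagonal_weight = diagonal_weight),
            class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("<skeleton_graph %d vertices, %d edges, d=%g>\n",
              nrow(x$coords), igraph::ecount(x$graph), x$diagonal_weight))
  invisible(x)
}

# Vertex index of pixel (x, y) in a skeleton_graph, or NA.
graph_vertex_id <- function(sg, p) {
  hit <- which(sg$coords[, 1] == p[1] & sg$coords[, 2] == p[2])
  if (length(hit) == 0L) NA_integer_ else hit[1]
}

#' Skeleton endpoints and intersection points
#'
#' An endpoint is a vertex of degree 1; an intersection (junction) is a
#' vertex of degree 3 or more.
#'
#' @param graph A `skeleton_graph`.
#' @return Matrix of 0-based `(x, y)` coordinates (possibly 0 rows).
#' @export
skeleton_endpoints <- function(graph) {
  deg <- igraph::degree(graph$graph)
  graph$coords[deg == 1L, , drop = FALSE]
}

#' @rdname skeleton_endpoints
#' @export
skeleton_intersections <- function(graph) {
  deg <- igraph::degree(graph$graph)
  graph$coords[deg >= 3L, , drop = FALSE]
}

#' Euclidean distance between a pixel and a skeleton graph
#'
#' The minimum Euclidean distance from `v` to any vertex of `other`.
#'
#' @param v `(x, y)` pixel.
#' @param other A `skeleton_graph` with at least one vertex.
#' @return Non-negative real.
#' @export
vertex_graph_distance <- function(v, other) {
  if (nrow(other$coords) == 0L)
    stop("vertex_graph_distance: empty graph")
  min(sqrt((other$coords[, 1] - v[1])^2 + (other$coords[, 2] - v[2])^2))
}

#' Geodesic distance between two skeleton pixels
#'
#' Sum of edge weights along the shortest path in the skeleton graph
#' (Dijkstra).  An error is raised if the two pixels lie in different
#' connected components.
#'
#' @param graph A `skeleton_graph`.
#' @param u,v `(x, y)` pixels that are vertices of `graph`.
#' @return Non-negative real.
#' @export
geodesic_distance <- function(graph, u, v) {
  iu <- graph_vertex_id(graph, u); iv <- graph_vertex_id(graph, v)
  if (is.na(iu) || is.na(iv))
    stop("geodesic_distance: pixel is not a vertex of the graph")
  d <- igraph::distances(graph$graph, v = iu, to = iv, mode = "all",
                         algorithm = "dijkstra")[1, 1]
  if (!is.finite(d)) stop("geodesic_distance: vertices are disconnected")
  d
}

# order rows by (row, col) i.e. (y, x) — the deterministic tie-break.
lex_first <- function(coords, which_rows) {
  sub <- coords[which_rows, , drop = FALSE]
  ord <- order(sub[, 2], sub[, 1])
  sub[ord[1], ]
}

#' Radicle pixel length from coat and radicle masks
#'
#' Measures the radicle as the skeleton-graph geodesic between the radicle
#' skeleton endpoint farthest from the seed-coat skeleton (the root tip)
#' and the junction closest to the coat skeleton (the emergence point).
#' Both masks are thinned, graphed, and then: the tip `p_e` is the
#' endpoint of the radicle graph maximizing the vertex-to-graph Euclidean
#' distance to the coat graph; the junction `p_i` is the intersection
#' vertex minimizing that distance, restricted to the connected component
#' of `p_e`.  Unbranched skeletons have no junction; the component vertex
#' nearest the coat skeleton is used instead and the measurement flagged
#' `no_intersection_fallback`.  All coordinate ties break to the smallest
#' (row, col).
#'
#' @param coat_mask Logical matrix, non-empty.
#' @param radicle_mask Logical matrix; empty yields length 0 with flag
#'   `no_radicle`.
#' @param diagonal_weight Diagonal edge weight (default 2; `sqrt(2)` gives
#'   Euclidean polyline lengths).
#' @return A `radicle_measurement`: list with `p_e`, `p_i` (0-based
#'   `(x, y)` or NULL), `pixel_length`, `flags`.
#' @export
radicle_pixel_length <- function(coat_mask, radicle_mask, diagonal_weight = 2) {
  if (!any(coat_mask)) stop("radicle_pixel_length: empty coat mask")
  flags <- character(0)
  empty <- function(flags) structure(
    list(p_e = NULL, p_i = NULL, pixel_length = 0, flags = flags),
    class = "radicle_measurement")
  if (!any(radicle_mask)) return(empty("no_radicle"))

  s_r <- thin_mask(radicle_mask)
  if (!any(s_r)) return(empty("no_radicle"))
  s_s <- thin_mask(coat_mask)
  if (!any(s_s)) s_s <- coat_mask  # thinning annihilated a tiny blob; use the mask

  g_s <- build_skeleton_graph(s_s, diagonal_weight)
  g_r <- build_skeleton_graph(s_r, diagonal_weight)

  dist_to_coat <- sqrt(outer(g_r$coords[, 1], g_s$coords[, 1], "-")^2 +
                       outer(g_r$coords[, 2], g_s$coords[, 2], "-")^2)
  dmin <- apply(dist_to_coat, 1, min)

  deg <- igraph::degree(g_r$graph)
  ep <- which(deg == 1L)
  if (length(ep) == 0L) ep <- seq_len(nrow(g_r$coords))  # cycle: no endpoints
  # tip: endpoint farthest from the coat skeleton, ties -> smallest (row, col)
  best <- max(dmin[ep])
  cand <- ep[dmin[ep] >= best - 1e-9]
  p_e <- lex_first(g_r$coords, cand)
  ie <- graph_vertex_id(g_r, p_e)

  comp <- igraph::components(g_r$graph)
  if (comp$no > 1L) flags <- c(flags, "skeleton_disconnected")
  in_comp <- which(comp$membership == comp$membership[ie])

  inter <- in_comp[deg[in_comp] >= 3L]
  if (length(inter) > 0L) {
    best <- min(dmin[inter])
    cand <- inter[dmin[inter] <= best + 1e-9]
    p_i <- lex_first(g_r$coords, cand)
  } else {
    flags <- c(flags, "no_intersection_fallback")
    best <- min(dmin[in_comp])
    cand <- in_comp[dmin[in_comp] <= best + 1e-9]
    p_i <- lex_first(g_r$coords, cand)
  }
  l_p <- geodesic_distance(g_r, p_e, p_i)
  structure(list(p_e = unname(p_e), p_i = unname(p_i), pixel_length = l_p,
                 flags = flags),
            class = "radicle_measurement")
}

#' @export
print.radicle_measurement <- function(x, ...) {
  cat(sprintf("<radicle_measurement l_p=%.2f px%s>\n", x$pixel_length,
              if (length(x$flags)) paste0(" [", flags_to_string(x$flags), "]") else ""))
  invisible(x)
}
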