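#' Triangulated surface mesh
#'
#' Container for a triangulated hemisphere surface: vertex coordinates in mm
#' and faces as 1-based vertex index triples. Generated icospheres carry their
#' subdivision order, which enables nested-ordering downsampling.
#'
#' @param vertices Numeric matrix, n x 3, vertex coordinates in mm.
#' @param faces Integer matrix, m x 3, 1-based vertex indices.
#' @param hemisphere `"left"` or `"right"`.
#' @param subdivision_order Integer >= 0 for generated icospheres, else `NULL`.
#' @param validate Check face indices and connectivity (default `TRUE`).
#' @return An object of class `surface_mesh` with elements `vertices`, `faces`,
#'   `hemisphere`, `subdivision_order`, `id`.
#' @export
surface_mesh <- function(vertices, faces, hemisphere = c("left", "right"),
                         subdivision_order = NULL, validate = TRUE) {
  hemisphere <- match.arg(hemisphere)
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stopf("'vertices' must be an n x 3 matrix")
  if (ncol(faces) != 3L) stopf("'faces' must be an m x 3 matrix")
  n <- nrow(vertices)
  if (validate) {
    if (any(faces < 1L) || any(faces > n))
      stopf("face indices must lie in [1, %d]", n)
    if (!mesh_is_connected(n, faces))
      stopf("mesh must be a single connected component")
  }
  id <- if (!is.null(subdivision_order)) {
    sprintf("ico%d_%s", subdivision_order, hemisphere)
  } else {
    sprintf("mesh%d_%s", n, hemisphere)
  }
  structure(
    list(vertices = vertices, faces = faces, hemisphere = hemisphere,
         subdivision_order = subdivision_order, id = id),
    class = "surface_mesh"
  )
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh '%s': %d vertices, %d faces, %s hemisphere%s\n",
              x$id, nrow(x$vertices), nrow(x$faces), x$hemisphere,
              if (!is.null(x$subdivision_order))
                sprintf(", icosphere order %d", x$subdivision_order) else ""))
  invisible(x)
}

n_vertices <- function(mesh) nrow(mesh$vertices)

# Level-synchronous BFS over face-derived edges; O(V + E) overall.
mesh_is_connected <- function(n, faces) {
  nbr <- adjacency_list_from_faces(n, faces)
  visited <- logical(n)
  visited[1L] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nxt <- unique(unlist(nbr[frontier], use.names = FALSE))
    nxt <- nxt[!visited[nxt]]
    visited[nxt] <- TRUE
    frontier <- nxt
  }
  all(visited)
}

edge_table <- function(faces) {
  e <- rbind(faces[, c(1L, 2L)], faces[, c(2L, 3L)], faces[, c(3L, 1L)])
  key <- pmin(e[, 1L], e[, 2L]) * 2^21 + pmax(e[, 1L], e[, 2L])
  e[!duplicated(key), , drop = FALSE]
}

adjacency_list_from_faces <- function(n, faces) {
  e <- edge_table(faces)
  from <- c(e[, 1L], e[, 2L])
  to <- c(e[, 2L], e[, 1L])
  unname(split(to, factor(from, levels = seq_len(n))))
}

#' Per-vertex neighbour sets of a mesh
#'
#' @param mesh A [surface_mesh()].
#' @return List of length `n_vertices`; element i holds the 1-based indices of
#'   the vertices sharing an edge with vertex i.
#' @export
vertex_adjacency <- function(mesh) {
  adjacency_list_from_faces(n_vertices(mesh), mesh$faces)
}

icosahedron <- function(radius = 100) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2)) * radius
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  list(vertices = v, faces = f)
}

#' Build an icosphere surface mesh
#'
#' Repeated 1-to-4 triangle subdivision of a regular icosahedron projected to a
#' sphere of radius 100 mm. Vertex ordering is nested: the vertices of an
#' order-k icosphere are exactly the first `10 * 4^k + 2` vertices of any
#' higher order, which is what [downsample_map()] relies on. An order-k sphere
#' has `10 * 4^k + 2` vertices and `20 * 4^k` faces.
#'
#' @param order Subdivision order, integer in 0..7 (order 7 gives 163,842
#'   vertices, the resolution of a standard average cortical surface; higher
#'   orders are refused as a memory guard).
#' @param hemisphere `"left"` or `"right"` (metadata only; both hemispheres use
#'   the same stand-in sphere geometry).
#' @param radius Sphere radius in mm (default 100).
#' @return A [surface_mesh()] with `subdivision_order = order`.
#' @export
build_icosphere <- function(order, hemisphere = c("left", "right"),
                            radius = 100) {
  hemisphere <- match.arg(hemisphere)
  order <- as.integer(order)
  if (length(order) != 1L || is.na(order) || order < 0L)
    stopf("'order' must be a single integer >= 0")
  if (order > 7L)
    stopf("icosphere order %d refused: order <= 7 (163,842 vertices) supported",
          order)
  ico <- icosahedron(radius)
  v <- ico$vertices
  f <- ico$faces
  for (k in seq_len(order)) {
    n <- nrow(v)
    # unique undirected edges; midpoints appended after existing vertices,
    # preserving the nested ordering across subdivision levels
    e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
    a <- pmin(e[, 1L], e[, 2L]); b <- pmax(e[, 1L], e[, 2L])
    key <- a * 2^21 + b
    ukey <- unique(key)
    idx <- match(key, ukey)                  # midpoint id per directed edge
    first <- !duplicated(key)
    mids <- (v[a[first], , drop = FALSE] + v[b[first], , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids^2)) * radius
    v <- rbind(v, mids)
    m <- n + idx                             # midpoint vertex index per f-edge
    nf <- nrow(f)
    m12 <- m[seq_len(nf)]
    m23 <- m[nf + seq_len(nf)]
    m31 <- m[2L * nf + seq_len(nf)]
    f <- rbind(
      cbind(f[, 1L], m12, m31),
      cbind(f[, 2L], m23, m12),
      cbind(f[, 3L], m31, m23),
      cbind(m12, m23, m31)
    )
  }
  surface_mesh(v, f, hemisphere, subdivision_order = order, validate = FALSE)
}

#' Per-vertex surface areas
#'
#' Each vertex receives one third of the area of every incident triangle, the
#' standard surface-statistics convention; vertex areas therefore sum exactly
#' to the total triangle area.
#'
#' @param mesh A [surface_mesh()].
#' @return Numeric vector of vertex areas in mm^2.
#' @export
vertex_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  e2 <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  cx <- e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L]
  cy <- e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L]
  cz <- e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L]
  fa <- sqrt(cx^2 + cy^2 + cz^2) / 2
  if (any(fa == 0)) warnf("%d degenerate zero-area face(s)", sum(fa == 0))
  third <- rep(fa / 3, 3L)
  res <- numeric(n_vertices(mesh))
  acc <- rowsum(third, group = as.vector(f), reorder = TRUE)
  res[as.integer(rownames(acc))] <- acc[, 1L]
  res
}

total_area <- function(mesh) sum(vertex_areas(mesh))

mean_edge_length <- function(mesh) {
  e <- edge_table(mesh$faces)
  d <- mesh$vertices[e[, 1L], , drop = FALSE] -
    mesh$vertices[e[, 2L], , drop = FALSE]
  mean(sqrt(rowSums(d^2)))
}

mean_sq_edge_length <- function(mesh) {
  e <- edge_table(mesh$faces)
  d <- mesh$vertices[e[, 1L], , drop = FALSE] -
    mesh$vertices[e[, 2L], , drop = FALSE]
  mean(rowSums(d^2))
}

#' Geodesic distances from a vertex
#'
#' On generated icospheres the exact great-circle distance is used; on general
#' meshes distances are graph shortest paths along edges (Dijkstra), an upper
#' bound on the true geodesic adequate for small meshes.
#'
#' @param mesh A [surface_mesh()].
#' @param from Source vertex index (1-based).
#' @return Numeric vector of distances in mm to every vertex.
#' @export
geodesic_distances <- function(mesh, from) {
  v <- mesh$vertices
  if (!is.null(mesh$subdivision_order)) {
    r <- sqrt(sum(v[from, ]^2))
    cosang <- pmin(1, pmax(-1, (v %*% v[from, ]) / (sqrt(rowSums(v^2)) * r)))
    return(as.numeric(r * acos(cosang)))
  }
  n <- n_vertices(mesh)
  nbr <- vertex_adjacency(mesh)
  dist <- rep(Inf, n)
  dist[from] <- 0
  done <- logical(n)
  for (i in seq_len(n)) {
    u <- which.min(ifelse(done, Inf, dist))
    if (!is.finite(dist[u])) break
    done[u] <- TRUE
    for (w in nbr[[u]]) {
      alt <- dist[u] + sqrt(sum((v[u, ] - v[w, ])^2))
      if (alt < dist[w]) dist[w] <- alt
    }
  }
  dist
}

#' Geodesic disc mask
#'
#' @param mesh A [surface_mesh()].
#' @param center Center vertex index (1-based).
#' @param radius_mm Disc radius in mm.
#' @return Logical vertex mask.
#' @export
geodesic_disc <- function(mesh, center, radius_mm) {
  if (radius_mm <= 0) stopf("'radius_mm' must be > 0")
  geodesic_distances(mesh, center) <= radius_mm
}

nearest_vertex <- function(mesh, direction) {
  u <- direction / sqrt(sum(direction^2))
  which.max(mesh$vertices %*% u)
}

#' Connected components of a binary vertex mask
#'
#' Maximal connected vertex sets under mesh edge adjacency restricted to the
#' mask; the building block of cluster-level inference. Cluster area is the
#' sum of member vertex areas.
#'
#' @param mesh A [surface_mesh()].
#' @param mask Logical (or 0/1) vertex mask.
#' @param stat Optional per-vertex statistic map; if given, each cluster
#'   reports its peak absolute value.
#' @param adj Optional precomputed [vertex_adjacency()] list.
#' @param areas Optional precomputed [vertex_areas()] vector.
#' @return A `cluster_table`: data frame with columns `cluster`, `n_vertices`,
#'   `area_mm2`, `peak_stat`, `p_cluster` (NA until corrected) and a list
#'   column `vertices` of member indices.
#' @export
connected_components <- function(mesh, mask, stat = NULL, adj = NULL,
                                 areas = NULL) {
  n <- n_vertices(mesh)
  mask <- as.logical(mask)
  if (length(mask) != n) stopf("mask length %d != %d vertices", length(mask), n)
  if (is.null(adj)) adj <- vertex_adjacency(mesh)
  if (is.null(areas)) areas <- vertex_areas(mesh)
  comp <- integer(n)                     # 0 = unlabelled / not in mask
  ncomp <- 0L
  queue <- integer(n)
  for (s in which(mask)) {
    if (comp[s] != 0L) next
    ncomp <- ncomp + 1L
    comp[s] <- ncomp
    queue[1L] <- s
    head <- 1L; tail <- 1L
    while (head <= tail) {
      u <- queue[head]; head <- head + 1L
      for (w in adj[[u]]) {
        if (mask[w] && comp[w] == 0L) {
          comp[w] <- ncomp
          tail <- tail + 1L
          queue[tail] <- w
        }
      }
    }
  }
  members <- if (ncomp > 0L) {
    split(which(comp > 0L), comp[comp > 0L])
  } else {
    list()
  }
  out <- data.frame(
    cluster = seq_len(ncomp),
    n_vertices = vapply(members, length, integer(1)),
    area_mm2 = vapply(members, function(ix) sum(areas[ix]), numeric(1)),
    peak_stat = if (is.null(stat)) rep(NA_real_, ncomp) else
      vapply(members, function(ix) max(abs(stat[ix])), numeric(1)),
    p_cluster = rep(NA_real_, ncomp)
  )
  out$vertices <- unname(members)
  class(out) <- c("cluster_table", "data.frame")
  out
}

#' Downsample a vertex map between nested icospheres
#'
#' Icospheres built by [build_icosphere()] are nested: an order-k sphere's
#' vertices are the first `10 * 4^k + 2` vertices of any finer sphere, so
#' downsampling is subsetting (e.g. 163,842 -> 2,562 vertices for order
#' 7 -> 4).
#'
#' @param map Numeric vertex map on an order-k icosphere.
#' @param mesh The icosphere [surface_mesh()] the map is bound to.
#' @param target_order Integer < k.
#' @return The map restricted to the order-`target_order` vertex set.
#' @export
downsample_map <- function(map, mesh, target_order) {
  if (is.null(mesh$subdivision_order))
    stopf("downsampling requires a generated icosphere mesh")
  k <- mesh$subdivision_order
  target_order <- as.integer(target_order)
  if (target_order >= k || target_order < 0L)
    stopf("'target_order' must be in [0, %d)", k)
  if (length(map) != n_vertices(mesh))
    stopf("map length %d != %d vertices", length(map), n_vertices(mesh))
  map[seq_len(10L * 4L^target_order + 2L)]
}
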