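#' Construct a TriSurface
#'
#' @param vertices numeric matrix of vertex positions (n x 3, mm).
#' @param triangles integer matrix of 1-based triangle indices (m x 3).
#' @return a validated [TriSurface-class] object.
#' @export
triSurface <- function(vertices, triangles) {
  v <- as.matrix(vertices); dimnames(v) <- NULL
  f <- as.matrix(triangles); dimnames(f) <- NULL
  storage.mode(f) <- "integer"
  new("TriSurface", vertices = v, triangles = f)
}

#' Construct a ScalarMap
#'
#' @param values numeric vector, one value per vertex.
#' @param units unit string ("" = dimensionless).
#' @return a [ScalarMap-class].
#' @export
scalarMap <- function(values, units = "") {
  new("ScalarMap", values = as.numeric(values), units = units)
}

# areas of all triangles via the cross product; used by validity, so plain
# matrices in and numeric out
triangleAreas <- function(v, f) {
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Total surface area of a mesh
#' @param surface a [TriSurface-class].
#' @return total area in mm^2.
#' @export
surfaceArea <- function(surface) {
  sum(triangleAreas(surface@vertices, surface@triangles))
}

#' Undirected edge list of a mesh
#'
#' @param surface a [TriSurface-class].
#' @return integer matrix (n_edges x 2) with i < j, each undirected edge once.
#' @export
meshEdges <- function(surface) {
  f <- surface@triangles
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  key <- (e[, 1] - 1) * nrow(surface@vertices) + e[, 2]
  e[!duplicated(key), , drop = FALSE]
}

#' Check that a mesh is a closed, consistently oriented 2-manifold
#'
#' Every undirected edge must be shared by exactly two triangles and be
#' traversed once in each direction.
#'
#' @param surface a [TriSurface-class].
#' @return logical.
#' @export
isClosedManifold <- function(surface) {
  f <- surface@triangles
  he <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])  # directed half-edges
  key <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  tab <- table(key)
  if (any(tab != 2L)) return(FALSE)
  # orientation: each directed half-edge must be unique
  dkey <- paste(he[, 1], he[, 2])
  !anyDuplicated(dkey)
}

#' Outward vertex normals (angle-weighted average of face normals)
#' @param surface a [TriSurface-class].
#' @return n x 3 matrix of unit normals.
#' @export
vertexNormals <- function(surface) {
  v <- surface@vertices; f <- surface@triangles
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n <- matrix(0, nrow(v), 3)
  for (k in 1:3) {
    for (d in 1:3) {
      acc <- rowsum(fn[, d], f[, k])
      idx <- as.integer(rownames(acc))
      n[idx, d] <- n[idx, d] + acc[, 1]
    }
  }
  n / pmax(sqrt(rowSums(n^2)), .Machine$double.eps)
}

#' Per-vertex surface area
#'
#' One third of the summed areas of the triangles incident to each vertex;
#' the vertex areas partition the mesh, so they sum exactly to the total
#' surface area.
#'
#' @param surface a [TriSurface-class].
#' @return a [ScalarMap-class] in mm^2.
#' @export
vertexArea <- function(surface) {
  v <- surface@vertices; f <- surface@triangles
  ta <- triangleAreas(v, f)
  av <- numeric(nrow(v))
  for (k in 1:3) {
    acc <- rowsum(ta, f[, k])
    idx <- as.integer(rownames(acc))
    av[idx] <- av[idx] + acc[, 1] / 3
  }
  scalarMap(av, "mm^2")
}

#' Edge-weighted graph of a mesh
#' @param surface a [TriSurface-class].
#' @return an igraph graph with edge attribute `weight` = Euclidean length.
#' @keywords internal
surfaceGraph <- function(surface) {
  e <- meshEdges(surface)
  w <- sqrt(rowSums((surface@vertices[e[, 1], , drop = FALSE] -
                     surface@vertices[e[, 2], , drop = FALSE])^2))
  igraph::graph_from_edgelist(e, directed = FALSE) |>
    igraph::set_edge_attr("weight", value = w)
}

#' Geodesic distances on the mesh edge graph
#'
#' Dijkstra shortest paths with edge-length weights, from `from` vertices
#' (default: all) to all vertices.  An approximation to exact surface
#' geodesics that is adequate at the package's target mesh resolutions.
#'
#' @param surface a [TriSurface-class].
#' @param from integer vertex ids (default all vertices).
#' @return numeric matrix length(from) x nVertices.
#' @export
geodesicDistances <- function(surface, from = seq_len(nrow(surface@vertices))) {
  g <- surfaceGraph(surface)
  igraph::distances(g, v = from, algorithm = "dijkstra")
}

#' Discrete mean curvature via the cotangent Laplacian
#'
#' The magnitude of the cotangent-weighted Laplace-Beltrami operator applied
#' to the coordinates equals twice the mean curvature normal; the sign is
#' taken from its projection on the outward vertex normal (positive where
#' the surface bends like a sphere seen from outside).
#'
#' @param surface a [TriSurface-class].
#' @return a [ScalarMap-class] in 1/mm.
#' @export
computeMeanCurvature <- function(surface) {
  v <- surface@vertices; f <- surface@triangles
  nv <- nrow(v)
  # cotangent at each triangle corner
  cot3 <- function(p, q, r) {  # angle at p
    u <- q - p; w <- r - p
    cu <- rowSums(u * w)
    cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
                u[, 3] * w[, 1] - u[, 1] * w[, 3],
                u[, 1] * w[, 2] - u[, 2] * w[, 1])
    cu / pmax(sqrt(rowSums(cr^2)), .Machine$double.eps)
  }
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  c1 <- cot3(p1, p2, p3); c2 <- cot3(p2, p3, p1); c3 <- cot3(p3, p1, p2)
  # assemble sparse cotangent weights: edge (i,j) opposite corner k gets cot_k
  ii <- c(f[, 2], f[, 3], f[, 3], f[, 1], f[, 1], f[, 2])
  jj <- c(f[, 3], f[, 2], f[, 1], f[, 3], f[, 2], f[, 1])
  ww <- c(c1, c1, c2, c2, c3, c3) / 2
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = ww, dims = c(nv, nv))
  deg <- Matrix::rowSums(W)
  lap <- as.matrix(W %*% v) - deg * v   # sum_j w_ij (x_j - x_i)
  amix <- mapValues(vertexArea(surface))
  hn <- lap / amix                      # Laplace-Beltrami of coordinates = -2 H n
  nrm <- vertexNormals(surface)
  h <- sqrt(rowSums(hn^2)) / 2          # |hn| = 2 H
  sgn <- ifelse(rowSums(hn * nrm) <= 0, 1, -1)  # Laplacian points inward on a sphere
  scalarMap(h * sgn, "1/mm")
}

#' Icosphere mesh
#'
#' Subdivided icosahedron projected to the sphere; the base icosahedron is
#' mirror-symmetric in each coordinate plane, and midpoint subdivision
#' preserves that symmetry, so left/right vertex correspondence across
#' x = 0 is exact (see [mirrorCorrespondence()]).
#'
#' @param level integer subdivision level (>= 0); vertex count is
#'   `10 * 4^level + 2`.
#' @param radius sphere radius in mm.
#' @return a [TriSurface-class].
#' @export
icosphere <- function(level = 3L, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  storage.mode(f) <- "integer"
  for (i in seq_len(level)) {
    nv <- nrow(v)
    e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    ek <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    ue <- unique(ek)
    mid <- (v[ue[, 1], , drop = FALSE] + v[ue[, 2], , drop = FALSE]) / 2
    mid <- mid / sqrt(rowSums(mid^2))
    key <- as.integer(ue[, 1]) * (nv + 1L) + as.integer(ue[, 2])
    lookup <- setNames(nv + seq_len(nrow(ue)), key)
    mids <- matrix(
      lookup[as.character(as.integer(ek[, 1]) * (nv + 1L) + as.integer(ek[, 2]))],
      ncol = 3)  # per-face midpoints for edges 12, 23, 31
    nfc <- nrow(f)
    m12 <- mids[seq_len(nfc)]
    m23 <- mids[nfc + seq_len(nfc)]
    m31 <- mids[2 * nfc + seq_len(nfc)]
    f <- rbind(cbind(f[, 1], m12, m31),
               cbind(f[, 2], m23, m12),
               cbind(f[, 3], m31, m23),
               cbind(m12, m23, m31))
    v <- rbind(v, mid)
  }
  triSurface(v * radius, f)
}

#' Left/right mirror correspondence of a symmetric mesh
#'
#' Finds, for each vertex, the vertex whose position is its reflection
#' across the given coordinate plane.  Errors if any match is farther than
#' `tol` (the mesh is then not mirror-symmetric and no correspondence
#' exists).
#'
#' @param surface a [TriSurface-class].
#' @param axis 1, 2 or 3: the coordinate negated by the reflection.
#' @param tol matching tolerance in mm.
#' @return integer vector `corr` with `corr[i]` = mirrored vertex of `i`.
#' @export
mirrorCorrespondence <- function(surface, axis = 1L, tol = 1e-6) {
  v <- surface@vertices
  m <- v
  m[, axis] <- -m[, axis]
  # nearest-neighbour match through a coarse spatial hash (robust to fp noise)
  h <- max(3 * tol, max(apply(v, 2, function(x) diff(range(x)))) / 64)
  cell <- function(x) floor(x / h)
  cv <- cell(v)
  keyv <- paste(cv[, 1], cv[, 2], cv[, 3])
  buckets <- split(seq_len(nrow(v)), keyv)
  corr <- integer(nrow(v))
  cm <- cell(m)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (i in seq_len(nrow(m))) {
    cand <- integer(0)
    for (o in seq_len(nrow(off))) {
      k <- paste(cm[i, 1] + off[o, 1], cm[i, 2] + off[o, 2], cm[i, 3] + off[o, 3])
      b <- buckets[[k]]
      if (!is.null(b)) cand <- c(cand, b)
    }
    if (!length(cand))
      stop("no mirror correspondence: mesh is not symmetric about axis ", axis)
    d2 <- rowSums((v[cand, , drop = FALSE] -
                   matrix(m[i, ], length(cand), 3, byrow = TRUE))^2)
    j <- cand[which.min(d2)]
    if (min(d2) > tol^2)
      stop("no mirror correspondence: mesh is not symmetric about axis ", axis,
           " at tolerance ", tol)
    corr[i] <- j
  }
  corr
}
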