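#' Construct a triangle mesh
#'
#' The central data structure of the package: an indexed triangle mesh with
#' vertex coordinates in millimetres. Vertex and triangle indices are
#' 1-based. Meshes are open shells in general; closed surfaces are also
#' valid.
#'
#' @param vertices numeric matrix, n x 3, vertex coordinates (mm).
#' @param triangles integer matrix, m x 3, vertex indices (1-based).
#' @param normals optional numeric matrix, n x 3, unit per-vertex normals.
#' @param validate check invariants (default `TRUE`).
#' @return An object of class `trimesh` with components `vertices`,
#'   `triangles` and optionally `normals`.
#' @examples
#' m <- trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
#'              rbind(c(1L, 2L, 3L)))
#' n_vertices(m)
#' @export
trimesh <- function(vertices, triangles, normals = NULL, validate = TRUE) {
  vertices <- as_xyz_matrix(vertices, "vertices")
  triangles <- matrix(as.integer(triangles), ncol = 3,
                      dimnames = NULL,
                      nrow = if (is.null(dim(triangles))) length(triangles) / 3
                             else nrow(triangles))
  m <- structure(list(vertices = vertices, triangles = triangles,
                      normals = normals), class = "trimesh")
  if (validate) validate_trimesh(m)
  m
}

as_xyz_matrix <- function(x, what) {
  x <- as.matrix(x)
  if (ncol(x) != 3) stop(what, " must have 3 columns", call. = FALSE)
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  x
}

validate_trimesh <- function(m) {
  v <- m$vertices; f <- m$triangles
  if (nrow(v) < 1) stop("mesh has no vertices", call. = FALSE)
  if (anyNA(v)) stop("mesh vertices contain NA", call. = FALSE)
  if (nrow(f) > 0) {
    if (min(f) < 1 || max(f) > nrow(v))
      stop("triangle index out of range", call. = FALSE)
    if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]))
      stop("triangle with repeated vertex index", call. = FALSE)
  }
  if (!is.null(m$normals)) {
    if (nrow(m$normals) != nrow(v))
      stop("normals must be one per vertex", call. = FALSE)
    len <- sqrt(rowSums(m$normals^2))
    ok <- is.na(len) | abs(len - 1) < 1e-6
    if (!all(ok)) stop("normals must be unit length", call. = FALSE)
  }
  invisible(m)
}

#' @rdname trimesh
#' @param m,x a `trimesh`.
#' @export
n_vertices <- function(m) nrow(m$vertices)

#' @rdname trimesh
#' @export
n_triangles <- function(m) nrow(m$triangles)

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("trimesh: %d vertices, %d triangles%s\n",
              n_vertices(x), n_triangles(x),
              if (is.null(x$normals)) "" else ", with normals"))
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("  bbox [mm]: x %.2f..%.2f  y %.2f..%.2f  z %.2f..%.2f\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

# Undirected edge key matrix (3m x 2, sorted within row) and owning triangle.
edge_table <- function(m) {
  f <- m$triangles
  e <- rbind(f[, c(1, 2), drop = FALSE],
             f[, c(2, 3), drop = FALSE],
             f[, c(3, 1), drop = FALSE])
  key <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  list(key = key, tri = rep.int(seq_len(nrow(f)), 3L),
       slot = rep(1:3, each = nrow(f)))
}

#' Boundary edges of an open mesh
#'
#' An edge is a boundary edge when it is incident to exactly one triangle;
#' boundary edges trace the outer border of an open shell and the rims of
#' its holes. They drive the auto-cropping of non-overlapping surface.
#'
#' @param m a `trimesh`.
#' @return Integer matrix, k x 2, each row an undirected boundary edge as a
#'   sorted pair of vertex indices; zero rows for a closed surface.
#' @examples
#' tri <- trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
#'                rbind(c(1L, 2L, 3L)))
#' boundary_edges(tri)  # all 3 edges
#' @export
boundary_edges <- function(m) {
  if (n_triangles(m) == 0)
    return(matrix(integer(0), ncol = 2))
  et <- edge_table(m)
  id <- paste(et$key[, 1], et$key[, 2])
  cnt <- table(id)
  keep <- cnt[id] == 1L
  unique(et$key[keep, , drop = FALSE])
}

#' Boundary loops of an open mesh
#'
#' Groups the boundary edges into closed loops by walking the boundary
#' edge graph. An open dome has one loop; each hole adds another.
#'
#' @param m a `trimesh`.
#' @return List of integer vectors, each the vertex indices of one loop in
#'   traversal order.
#' @export
boundary_loops <- function(m) {
  be <- boundary_edges(m)
  if (nrow(be) == 0) return(list())
  adj <- split(c(be[, 2], be[, 1]), c(be[, 1], be[, 2]))
  unvisited_edges <- new.env(parent = emptyenv())
  ekey <- function(a, b) paste(min(a, b), max(a, b))
  for (i in seq_len(nrow(be))) assign(ekey(be[i, 1], be[i, 2]), TRUE,
                                      envir = unvisited_edges)
  loops <- list()
  for (i in seq_len(nrow(be))) {
    if (!exists(ekey(be[i, 1], be[i, 2]), envir = unvisited_edges)) next
    start <- be[i, 1]
    loop <- start
    prev <- NA_integer_
    cur <- start
    repeat {
      nbrs <- adj[[as.character(cur)]]
      nxt <- NA_integer_
      for (cand in nbrs) {
        if (!is.na(prev) && cand == prev) next
        if (exists(ekey(cur, cand), envir = unvisited_edges)) {
          nxt <- cand
          break
        }
      }
      if (is.na(nxt)) break
      rm(list = ekey(cur, nxt), envir = unvisited_edges)
      if (nxt == start) break
      loop <- c(loop, nxt)
      prev <- cur
      cur <- nxt
    }
    loops[[length(loops) + 1]] <- loop
  }
  loops
}

# Per-triangle un-normalized normals (cross product; length = 2 * area).
triangle_normals_raw <- function(m) {
  v <- m$vertices; f <- m$triangles
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
        e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
        e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
}

#' Area-weighted per-vertex normals
#'
#' Each vertex normal interpolates the normals of its incident triangles,
#' weighted by triangle area, and is normalized to unit length. Orientation
#' follows the triangle winding. Isolated vertices (no incident
#' non-degenerate triangle) get an `NA` normal and are flagged.
#'
#' @param m a `trimesh`.
#' @return Numeric matrix n x 3 of unit normals, with attribute `isolated`:
#'   integer indices of vertices whose normal is undefined.
#' @export
vertex_normals <- function(m) {
  v <- m$vertices; f <- m$triangles
  tn <- triangle_normals_raw(m)  # area weighting comes for free
  acc <- matrix(0, nrow(v), 3)
  for (k in 1:3) {
    idx <- f[, k]
    acc[, 1] <- acc[, 1] + unname(tapply_sum(tn[, 1], idx, nrow(v)))
    acc[, 2] <- acc[, 2] + unname(tapply_sum(tn[, 2], idx, nrow(v)))
    acc[, 3] <- acc[, 3] + unname(tapply_sum(tn[, 3], idx, nrow(v)))
  }
  len <- sqrt(rowSums(acc^2))
  isolated <- which(len < 1e-300)
  len[len < 1e-300] <- NA_real_
  out <- acc / len
  attr(out, "isolated") <- isolated
  out
}

tapply_sum <- function(x, idx, n) {
  out <- numeric(n)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Rigid (or similarity) spatial transforms
#'
#' A rotation + translation pair, optionally with a uniform scale, mapping
#' points as `scale * rotation %*% p + translation`. Registration uses
#' rigid transforms by default; the scale slot supports the traditional
#' scaling step of Procrustes superimposition when explicitly enabled.
#'
#' @param rotation 3 x 3 orthonormal matrix with determinant +1.
#' @param translation length-3 numeric vector (mm).
#' @param scale positive scalar, default 1 (rigid motion).
#' @return An object of class `rigid_transform`.
#' @examples
#' t1 <- rigid_transform(rotation_about_z(pi / 6), c(1, 0, 0))
#' t2 <- invert_transform(t1)
#' compose_transforms(t2, t1)  # identity
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            scale = 1) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3,
            scale > 0)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation is not orthonormal", call. = FALSE)
  if (det(rotation) < 0)
    stop("rotation has negative determinant (reflection)", call. = FALSE)
  structure(list(rotation = rotation,
                 translation = as.numeric(translation),
                 scale = as.numeric(scale)),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @export
identity_transform <- function() rigid_transform()

#' @rdname rigid_transform
#' @param angle rotation angle in radians.
#' @export
rotation_about_z <- function(angle) {
  c_ <- cos(angle); s_ <- sin(angle)
  rbind(c(c_, -s_, 0), c(s_, c_, 0), c(0, 0, 1))
}

#' @rdname rigid_transform
#' @param axis rotation axis (any length-3 nonzero vector).
#' @export
rotation_about_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- rbind(c(0, -u[3], u[2]), c(u[3], 0, -u[1]), c(-u[2], u[1], 0))
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' @rdname rigid_transform
#' @param t2,t1 transforms; the composition applies `t1` first.
#' @export
compose_transforms <- function(t2, t1) {
  rigid_transform(rotation = t2$rotation %*% t1$rotation,
                  translation = t2$scale * t2$rotation %*% t1$translation +
                    t2$translation,
                  scale = t2$scale * t1$scale)
}

#' @rdname rigid_transform
#' @param t a `rigid_transform`.
#' @export
invert_transform <- function(t) {
  rinv <- t(t$rotation)
  rigid_transform(rotation = rinv,
                  translation = -(1 / t$scale) * rinv %*% t$translation,
                  scale = 1 / t$scale)
}

#' @rdname rigid_transform
#' @param points n x 3 matrix of points.
#' @export
transform_points <- function(points, t) {
  points <- as_xyz_matrix(points, "points")
  sweep(t$scale * points %*% t(t$rotation), 2, -t$translation)
}

#' @rdname rigid_transform
#' @export
transform_matrix <- function(t) {
  out <- diag(4)
  out[1:3, 1:3] <- t$scale * t$rotation
  out[1:3, 4] <- t$translation
  out
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2)))
  cat(sprintf(
    "rigid_transform: rotation %.3f rad, translation (%.3f, %.3f, %.3f) mm%s\n",
    ang, x$translation[1], x$translation[2], x$translation[3],
    if (x$scale != 1) sprintf(", scale %.4f", x$scale) else ""))
  invisible(x)
}

#' Apply a spatial transform to a mesh
#'
#' Maps every vertex as `scale * rotation %*% v + translation`; topology is
#' unchanged and any stored normals are rotated.
#'
#' @param m a `trimesh`.
#' @param t a `rigid_transform`.
#' @return The transformed `trimesh`.
#' @export
apply_transform <- function(m, t) {
  out <- m
  out$vertices <- transform_points(m$vertices, t)
  if (!is.null(m$normals)) out$normals <- m$normals %*% t(t$rotation)
  out
}

#' Drop degenerate (zero-area) triangles
#'
#' Zero-area triangles contribute no normal and break point-to-triangle
#' projection, so they are removed at load time with a warning.
#'
#' @param m a `trimesh`.
#' @param tol squared-area tolerance.
#' @return The cleaned `trimesh`.
#' @export
drop_degenerate_triangles <- function(m, tol = 1e-24) {
  if (n_triangles(m) == 0) return(m)
  a2 <- rowSums(triangle_normals_raw(m)^2)
  bad <- a2 <= tol
  if (any(bad)) {
    warning(sprintf("dropped %d degenerate triangle(s)", sum(bad)),
            call. = FALSE)
    m$triangles <- m$triangles[!bad, , drop = FALSE]
  }
  m
}
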