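#' Build a spatial index for point-to-surface queries
#'
#' Precomputes per-triangle centroids, circumradii and boundary incidence
#' so that repeated nearest-point-on-surface queries are fast. Queries are
#' exact: triangles are examined in ascending order of the provable lower
#' bound (distance to centroid minus circumradius) and the scan stops once
#' no remaining triangle can beat — or tie — the best hit, so results
#' match an exhaustive scan over all triangles.
#'
#' The index is immutable after construction and safe to reuse across any
#' number of queries.
#'
#' @param m a [trimesh] with at least one triangle.
#' @return An object of class `surface_index`.
#' @seealso [nearest_on_surface()], [pair_vertices()]
#' @export
build_index <- function(m) {
  validate_trimesh(m)
  if (n_triangles(m) == 0)
    stop("cannot index a mesh without triangles", call. = FALSE)
  v <- m$vertices; f <- m$triangles
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  centroids <- (a + b + c_) / 3
  radii <- sqrt(pmax(rowSums((a - centroids)^2),
                     rowSums((b - centroids)^2),
                     rowSums((c_ - centroids)^2)))
  # boundary incidence per triangle edge slot and per vertex
  et <- edge_table(m)
  id <- paste(et$key[, 1], et$key[, 2])
  cnt <- table(id)
  is_bnd <- as.vector(cnt[id] == 1L)
  edge_boundary <- matrix(FALSE, nrow(f), 3)
  edge_boundary[cbind(et$tri, et$slot)] <- is_bnd
  vert_boundary <- rep(FALSE, nrow(v))
  if (any(is_bnd)) vert_boundary[unique(as.vector(et$key[is_bnd, ]))] <- TRUE
  structure(list(mesh = m, centroids = centroids, radii = radii,
                 edge_boundary = edge_boundary,
                 vert_boundary = vert_boundary),
            class = "surface_index")
}

#' @export
print.surface_index <- function(x, ...) {
  cat(sprintf("surface_index over %d triangles (%d boundary edges)\n",
              nrow(x$mesh$triangles), sum(x$edge_boundary)))
  invisible(x)
}

as_surface_index <- function(x) {
  if (inherits(x, "surface_index")) x
  else if (inherits(x, "trimesh")) build_index(x)
  else stop("expected a trimesh or surface_index", call. = FALSE)
}

#' Exact nearest point on a triangulated surface
#'
#' For each query point, finds the closest point anywhere on the polygonal
#' surface — triangle interiors, edges and vertices included. Each hit
#' carries a uniqueness flag (`FALSE` when a second triangle attains the
#' same minimal distance, within a relative tolerance, at a surface point
#' more than `tie_separation` away — such query points map ambiguously and
#' are excluded from similarity computations) and a boundary flag (`TRUE`
#' when the closest point lies on a boundary edge or boundary vertex,
#' meaning the query point projects onto non-overlapping surface).
#'
#' @param points a single 3D point or an n x 3 matrix of query points (mm).
#' @param index a [build_index()] result (a bare [trimesh] is indexed on
#'   the fly).
#' @param tie_epsilon relative distance tolerance for tie detection.
#' @param tie_separation minimum spatial separation (mm) between two
#'   closest points for them to count as a genuine tie rather than the
#'   same point reached through adjacent triangles.
#' @return A data frame with one row per query: columns `x`, `y`, `z`
#'   (closest point), `distance`, `triangle`, `b1`, `b2`, `b3`
#'   (barycentric coordinates), `unique`, `on_boundary`.
#' @examples
#' tri <- trimesh(rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0)),
#'                rbind(c(1L, 2L, 3L)))
#' nearest_on_surface(c(1, 1, 1), tri)  # projects to (1, 1, 0), distance 1
#' @export
nearest_on_surface <- function(points, index, tie_epsilon = 1e-9,
                               tie_separation = 1e-6) {
  res <- nearest_raw(points, index, tie_epsilon, tie_separation)
  data.frame(x = res$closest[, 1], y = res$closest[, 2],
             z = res$closest[, 3], distance = res$distance,
             triangle = res$triangle, b1 = res$bary[, 1],
             b2 = res$bary[, 2], b3 = res$bary[, 3],
             unique = res$unique, on_boundary = res$on_boundary)
}

# Hot path used by ICP pairing: the raw C++ result without data.frame
# packaging.
nearest_raw <- function(points, index, tie_epsilon = 1e-9,
                        tie_separation = 1e-6) {
  index <- as_surface_index(index)
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  points <- as_xyz_matrix(points, "points")
  cpp_nearest_batch(index$mesh$vertices, index$mesh$triangles - 1L,
                    index$centroids, index$radii,
                    index$edge_boundary, index$vert_boundary,
                    points, tie_epsilon, tie_separation)
}

#' Pair source vertices with their nearest points on a target surface
#'
#' The pairing underlying both ICP and similarity measurement: every
#' (sampled) vertex of the source mesh is mapped to its closest point on
#' the target surface. Vertices with multiple nearest neighbors are always
#' excluded — they make the mapping non-deterministic and in real scans
#' amount to noise. With `crop = TRUE`, vertices whose nearest neighbor
#' lands on a boundary edge of the target are also excluded: such vertices
#' lie over surface the target does not cover (ragged borders, holes), and
#' keeping them would distort both registration and measurement.
#'
#' @param source a [trimesh] (or a plain n x 3 point matrix) whose
#'   vertices are queried.
#' @param target a `surface_index` (or [trimesh]) queried against.
#' @param sample_indices optional integer vector of source vertex indices
#'   to use (default: all vertices).
#' @param crop exclude vertices projecting onto the target boundary.
#' @param tie_epsilon,tie_separation passed to [nearest_on_surface()].
#' @return An object of class `pairing_set`: list with `indices` (retained
#'   source vertex indices), `source_points`, `closest` (matched points,
#'   matrices), `distance`, `n_excluded_tie`, `n_excluded_crop`.
#' @export
pair_vertices <- function(source, target, sample_indices = NULL,
                          crop = FALSE, tie_epsilon = 1e-9,
                          tie_separation = 1e-6) {
  target <- as_surface_index(target)
  src_pts <- if (inherits(source, "trimesh")) source$vertices
             else as_xyz_matrix(source, "source")
  if (is.null(sample_indices)) sample_indices <- seq_len(nrow(src_pts))
  stopifnot(all(sample_indices >= 1),
            all(sample_indices <= nrow(src_pts)))
  pts <- src_pts[sample_indices, , drop = FALSE]
  hits <- nearest_raw(pts, target, tie_epsilon, tie_separation)
  keep <- hits$unique
  n_tie <- sum(!keep)
  n_crop <- 0L
  if (crop) {
    cropped <- keep & hits$on_boundary
    n_crop <- sum(cropped)
    keep <- keep & !hits$on_boundary
  }
  if (!any(keep))
    stop("empty pairing: surfaces do not overlap sufficiently",
         call. = FALSE)
  structure(list(indices = sample_indices[keep],
                 source_points = pts[keep, , drop = FALSE],
                 closest = hits$closest[keep, , drop = FALSE],
                 distance = hits$distance[keep],
                 on_boundary = hits$on_boundary[keep],
                 n_excluded_tie = n_tie, n_excluded_crop = n_crop),
            class = "pairing_set")
}

#' @export
print.pairing_set <- function(x, ...) {
  cat(sprintf(
    "pairing_set: %d pairs (mean distance %.4f mm), excluded %d tie / %d crop\n",
    length(x$distance), mean(x$distance), x$n_excluded_tie,
    x$n_excluded_crop))
  invisible(x)
}
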