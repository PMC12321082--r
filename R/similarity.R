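#' Directional mean surface distance (distance cost function)
#'
#' The average Euclidean distance from the (reduced, optionally cropped)
#' vertices of `fi` to their nearest points on the surface of `fj`. The
#' reduction drops vertices with multiple nearest neighbors; cropping
#' additionally drops vertices whose nearest neighbor lies on a boundary
#' edge of `fj`, i.e. vertices over non-overlapping surface. This is the
#' quantity ICP minimizes and one arm of [mesh_distance()].
#'
#' @param fi a [trimesh] (source of vertices).
#' @param fj a `surface_index` or [trimesh] (target surface).
#' @param crop exclude vertices projecting onto the boundary of `fj`
#'   (default `TRUE`).
#' @param samples optional integer vector of `fi` vertex indices to use.
#' @return An object of class `directional_distance`: list with `value`
#'   (mm), `n_used`, `n_excluded_tie`, `n_excluded_crop`.
#' @export
d_avg <- function(fi, fj, crop = TRUE, samples = NULL) {
  pr <- pair_vertices(fi, fj, sample_indices = samples, crop = crop)
  structure(list(value = mean(pr$distance), n_used = length(pr$distance),
                 n_excluded_tie = pr$n_excluded_tie,
                 n_excluded_crop = pr$n_excluded_crop),
            class = "directional_distance")
}

#' @export
print.directional_distance <- function(x, ...) {
  cat(sprintf(
    "directional distance: %.4f mm over %d vertices (excluded %d tie / %d crop)\n",
    x$value, x$n_used, x$n_excluded_tie, x$n_excluded_crop))
  invisible(x)
}

#' Mutual surface distance (modified Hausdorff)
#'
#' A single symmetric dissimilarity of two open surfaces: the larger of
#' the two directional mean distances [d_avg()]. Averaging nearest-neighbor
#' distances instead of taking their supremum makes the measure robust to
#' noise and outliers, which the classic Hausdorff distance is not.
#'
#' @param fi,fj [trimesh] objects or `surface_index`es (an index carries
#'   its mesh, so either form works on either side).
#' @param crop auto-crop non-overlapping surface (default `TRUE`).
#' @return Distance in mm (non-negative; 0 for identical surfaces).
#' @export
mesh_distance <- function(fi, fj, crop = TRUE) {
  ii <- as_surface_index(fi)
  ij <- as_surface_index(fj)
  max(d_avg(ii$mesh, ij, crop = crop)$value,
      d_avg(ij$mesh, ii, crop = crop)$value)
}

#' Signed (relative) distance from points to a surface
#'
#' The nearest-neighbor distance with a sign: positive when the nearest
#' neighbor lies in the half-space of the vertex normal ("in front of" the
#' gauge surface), negative when behind. Used by the relative variant of
#' indirect measurement, where only one scalar per vertex needs caching.
#'
#' @param points n x 3 matrix of query points (mm).
#' @param normals n x 3 matrix of unit normals at those points.
#' @param f a `surface_index` or [trimesh].
#' @return A list with `value` (signed distances, mm; sign of the zero
#'   dot-product case is positive), `unique`, `on_boundary` per point.
#' @export
relative_distance <- function(points, normals, f) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  points <- as_xyz_matrix(points, "points")
  if (is.null(dim(normals))) normals <- matrix(normals, ncol = 3,
                                               byrow = TRUE)
  hits <- nearest_on_surface(points, f)
  vvec <- cbind(hits$x - points[, 1], hits$y - points[, 2],
                hits$z - points[, 3])
  sgn <- ifelse(rowSums(vvec * normals) >= 0, 1, -1)
  list(value = sgn * hits$distance, unique = hits$unique,
       on_boundary = hits$on_boundary)
}

#' Indirect pairwise distance through an average-face gauge
#'
#' Approximates the distance between two registered faces without
#' comparing them directly: every vertex of the average face `fa` is
#' projected onto both faces, and the per-vertex measure is averaged over
#' the vertices of `fa` with exactly one nearest neighbor on each face
#' (and, under cropping, neighbors not on a boundary edge).
#'
#' Two per-vertex measures are available: `"euclidean"` takes the distance
#' between the two closest points; `"relative"` takes the absolute
#' difference of the signed normal-referenced distances ([relative_distance()])
#' and needs only one cached scalar per vertex and face.
#'
#' @param fa the average (gauge) [trimesh]; for `method = "relative"` its
#'   vertex normals are computed if not stored.
#' @param fi,fj `surface_index`es or [trimesh]es, registered into the
#'   frame of `fa`.
#' @param method `"euclidean"` or `"relative"`.
#' @param crop exclude gauge vertices whose neighbor on either face lies
#'   on that face's boundary (default `TRUE`).
#' @return Distance in mm.
#' @seealso [build_cache()] and [indirect_matrix()] for the batch (N:N)
#'   form that amortizes the surface queries.
#' @export
indirect_distance <- function(fa, fi, fj, method = c("euclidean",
                                                     "relative"),
                              crop = TRUE) {
  method <- match.arg(method)
  cache <- build_cache(fa, list(fi, fj), method = method, crop = crop)
  indirect_matrix(cache)$matrix[1, 2]
}
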