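#' Precompute the nearest-neighbor cache over the average face
#'
#' One exact nearest-surface query per (average-face vertex, face) — cost
#' linear in the number of faces — whose results are stored so that all
#' pairwise distances can later be assembled without any further surface
#' queries. The `"euclidean"` method caches the closest 3D point itself;
#' the `"relative"` method caches only the signed scalar distance along
#' the average face's vertex normal, one number per record. A record is
#' valid when the nearest neighbor is unique and, under cropping, does not
#' lie on the face's boundary; invalid records never enter a mean.
#'
#' @param average the average (gauge) [trimesh]; vertex normals are
#'   computed if not stored (required by the relative method).
#' @param faces list of [trimesh] objects or `surface_index`es, registered
#'   into the average face's frame.
#' @param method `"euclidean"` or `"relative"`.
#' @param crop invalidate boundary-landing records (default `TRUE`).
#' @return An object of class `distance_cache`.
#' @seealso [indirect_matrix()]
#' @export
build_cache <- function(average, faces, method = c("euclidean",
                                                   "relative"),
                        crop = TRUE) {
  method <- match.arg(method)
  nf <- length(faces)
  if (nf < 1) stop("need at least one face", call. = FALSE)
  v <- average$vertices
  nv <- nrow(v)
  normals <- NULL
  if (method == "relative") {
    normals <- average$normals
    if (is.null(normals)) normals <- vertex_normals(average)
  }
  valid <- matrix(FALSE, nv, nf)
  points <- if (method == "euclidean") vector("list", nf) else NULL
  scalars <- if (method == "relative") matrix(NA_real_, nv, nf) else NULL
  for (k in seq_len(nf)) {
    hits <- nearest_on_surface(v, faces[[k]])
    ok <- hits$unique
    if (crop) ok <- ok & !hits$on_boundary
    if (method == "relative") {
      vvec <- cbind(hits$x - v[, 1], hits$y - v[, 2], hits$z - v[, 3])
      sgn <- ifelse(rowSums(vvec * normals) >= 0, 1, -1)
      ok <- ok & !is.na(rowSums(normals))
      scalars[, k] <- sgn * hits$distance
    } else {
      points[[k]] <- cbind(hits$x, hits$y, hits$z)
    }
    valid[, k] <- ok
    if (!any(ok))
      warning(sprintf("face %d has no valid cache record (unmeasurable)",
                      k), call. = FALSE)
  }
  structure(list(method = method, n_vertices = nv, n_faces = nf,
                 points = points, scalars = scalars, valid = valid,
                 face_names = names(faces)),
            class = "distance_cache")
}

#' @export
print.distance_cache <- function(x, ...) {
  cat(sprintf(
    "distance_cache (%s): %d average-face vertices x %d faces, %.1f%% valid\n",
    x$method, x$n_vertices, x$n_faces, 100 * mean(x$valid)))
  invisible(x)
}

#' Assemble the pairwise distance matrix from the cache
#'
#' Entry (i, j) is the mean, over the average-face vertices valid for both
#' face i and face j, of the per-vertex indirect measure: the Euclidean
#' distance between the two cached closest points, or the absolute
#' difference of the two cached signed distances. No surface queries are
#' performed; every cell is independent of the others, so any execution
#' order yields identical results. Pairs with no jointly valid vertex are
#' flagged missing (`NA`).
#'
#' @param cache a [build_cache()] result.
#' @return An object of class `distance_matrix`: `matrix` (symmetric, mm,
#'   zero diagonal), `counts` (jointly valid vertices per cell), `method`.
#' @export
indirect_matrix <- function(cache) {
  nf <- cache$n_faces
  if (nf < 2) stop("need at least two measurable faces", call. = FALSE)
  m <- matrix(0, nf, nf)
  counts <- matrix(0L, nf, nf)
  diag(counts) <- colSums(cache$valid)
  for (i in seq_len(nf - 1)) {
    for (j in (i + 1):nf) {
      jv <- cache$valid[, i] & cache$valid[, j]
      counts[i, j] <- counts[j, i] <- sum(jv)
      if (!any(jv)) {
        m[i, j] <- m[j, i] <- NA_real_
        next
      }
      val <- if (cache$method == "euclidean") {
        mean(sqrt(rowSums((cache$points[[i]][jv, , drop = FALSE] -
                           cache$points[[j]][jv, , drop = FALSE])^2)))
      } else {
        mean(abs(cache$scalars[jv, i] - cache$scalars[jv, j]))
      }
      m[i, j] <- m[j, i] <- val
    }
  }
  dimnames(m) <- list(cache$face_names, cache$face_names)
  structure(list(matrix = m, counts = counts, method = cache$method),
            class = "distance_matrix")
}

#' Direct pairwise distance matrices (validation baselines)
#'
#' Quadratic-cost reference computations against which the indirect gauge
#' measurement is validated; intended for small populations only.
#'
#' Mode `"FR"` assumes the faces are already batch-registered and only
#' measures: entry (i, j) is [mesh_distance()] with auto-cropping. Mode
#' `"BL"` registers each pair individually in both directions (i onto j
#' and j onto i) and keeps the direction with the smaller cropped
#' distance, mimicking the careful pairwise workflow.
#'
#' With `crop_to_average`, each directional mean is additionally
#' restricted to source vertices whose nearest neighbor on the average
#' face is valid (unique, non-boundary), so that the direct measurement
#' covers the same surface region as the gauge-based indirect one and the
#' two become comparable.
#'
#' @param faces list of [trimesh] objects (for `"FR"`, already registered).
#' @param mode `"FR"` or `"BL"`.
#' @param crop auto-crop non-overlapping surface (default `TRUE`).
#' @param crop_to_average optional average [trimesh]; restrict measurement
#'   to surface covered by it.
#' @param icp an [icp_config()] for `"BL"` registrations (default: full
#'   resolution, no sub-sampling).
#' @return A `distance_matrix` (see [indirect_matrix()]).
#' @export
direct_matrix <- function(faces, mode = c("FR", "BL"), crop = TRUE,
                          crop_to_average = NULL,
                          icp = icp_config(sampling = "none")) {
  mode <- match.arg(mode)
  nf <- length(faces)
  if (nf < 2) stop("need at least two faces", call. = FALSE)
  idx <- lapply(faces, as_surface_index)
  avg_masks <- NULL
  if (!is.null(crop_to_average)) {
    avg_idx <- as_surface_index(crop_to_average)
    avg_masks <- lapply(idx, function(ii) {
      hits <- nearest_on_surface(ii$mesh$vertices, avg_idx)
      which(hits$unique & !hits$on_boundary)
    })
  }
  pair_dist <- function(i, j) {
    da <- d_avg(idx[[i]]$mesh, idx[[j]], crop = crop,
                samples = if (is.null(avg_masks)) NULL else
                  avg_masks[[i]])$value
    db <- d_avg(idx[[j]]$mesh, idx[[i]], crop = crop,
                samples = if (is.null(avg_masks)) NULL else
                  avg_masks[[j]])$value
    max(da, db)
  }

  m <- matrix(0, nf, nf)
  counts <- matrix(0L, nf, nf)
  for (i in seq_len(nf - 1)) {
    for (j in (i + 1):nf) {
      val <- tryCatch({
        if (mode == "FR") {
          pair_dist(i, j)
        } else {
          # BL: bidirectional registration, keep the better direction
          fit_ij <- icp_register(faces[[i]], idx[[j]], icp)
          fit_ji <- icp_register(faces[[j]], idx[[i]], icp)
          mi <- build_index(apply_transform(faces[[i]], fit_ij$transform))
          mj <- build_index(apply_transform(faces[[j]], fit_ji$transform))
          d1 <- mesh_distance(mi, idx[[j]], crop = crop)
          d2 <- mesh_distance(mj, idx[[i]], crop = crop)
          min(d1, d2)
        }
      }, error = function(e) NA_real_)
      m[i, j] <- m[j, i] <- val
    }
  }
  dimnames(m) <- list(names(faces), names(faces))
  structure(list(matrix = m, counts = counts, method = mode),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  off <- x$matrix[upper.tri(x$matrix)]
  cat(sprintf(
    "distance_matrix (%s): %d faces, mean off-diagonal %.4f mm (%d missing)\n",
    x$method, nrow(x$matrix), mean(off, na.rm = TRUE), sum(is.na(off))))
  invisible(x)
}

#' Write a distance matrix to CSV
#'
#' The square form has a header row and column of face identifiers and
#' the full symmetric matrix; missing entries are written as empty cells,
#' never as 0. The long form has one row per unordered pair with the
#' jointly used vertex count.
#'
#' @param dm a `distance_matrix`.
#' @param path output CSV path.
#' @param long also write the long-format table next to `path` (suffix
#'   `_long.csv`).
#' @return `path`, invisibly.
#' @export
write_distance_csv <- function(dm, path, long = FALSE) {
  m <- dm$matrix
  ids <- rownames(m)
  if (is.null(ids)) ids <- sprintf("face_%02d", seq_len(nrow(m)))
  out <- vapply(m, function(x)
    if (is.na(x)) "" else format(x, digits = 10), character(1))
  dim(out) <- dim(m)
  df <- data.frame(face = ids, out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("face", ids)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (long) {
    iu <- which(upper.tri(m), arr.ind = TRUE)
    ldf <- data.frame(face_i = ids[iu[, 1]], face_j = ids[iu[, 2]],
                      distance = m[iu],
                      n_vertices = dm$counts[iu])
    write.csv(ldf, sub("\\.csv$", "_long.csv", path), row.names = FALSE,
              quote = FALSE)
  }
  invisible(path)
}
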