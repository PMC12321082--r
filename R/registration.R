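#' ICP configuration
#'
#' Settings for one-directional ICP registration. The defaults are the
#' recommended operating point for facial shells: at most 100 iterations,
#' termination when the mean pairing distance changes by less than
#' 0.05 mm between consecutive iterations, and random sub-sampling of the
#' moving mesh to 1000 vertices. Auto-cropping is disabled on the first
#' iteration unconditionally — with poor initial overlap the crop could
#' starve the pairing — and enabled from the second iteration on.
#'
#' @param max_iterations maximum ICP iterations (default 100).
#' @param delta_threshold absolute change in mean pairing distance (mm)
#'   below which ICP stops (default 0.05).
#' @param n_samples number of moving-mesh vertices used per registration
#'   (default 1000); the sample is drawn once, not per iteration.
#' @param sampling `"random"`, `"uniform_grid"`, `"curvature"` or `"none"`
#'   (all vertices).
#' @param crop_after_first auto-crop from iteration 2 onward (default
#'   `TRUE`).
#' @param seed RNG seed for sampling.
#' @param allow_scale estimate a uniform scale in addition to the rigid
#'   motion (default `FALSE`; distances are in mm and scaling would
#'   distort them).
#' @param init_centroid translate the moving mesh's centroid onto the
#'   fixed mesh's centroid before iterating (default `FALSE`; rough
#'   pre-alignment of the inputs is otherwise assumed).
#' @return A list of class `icp_config`.
#' @export
icp_config <- function(max_iterations = 100L, delta_threshold = 0.05,
                       n_samples = 1000L,
                       sampling = c("random", "uniform_grid", "curvature",
                                    "none"),
                       crop_after_first = TRUE, seed = 1L,
                       allow_scale = FALSE, init_centroid = FALSE) {
  sampling <- match.arg(sampling)
  stopifnot(max_iterations >= 1, delta_threshold > 0, n_samples >= 3)
  structure(list(max_iterations = as.integer(max_iterations),
                 delta_threshold = delta_threshold,
                 n_samples = as.integer(n_samples), sampling = sampling,
                 crop_after_first = isTRUE(crop_after_first),
                 seed = as.integer(seed),
                 allow_scale = isTRUE(allow_scale),
                 init_centroid = isTRUE(init_centroid)),
            class = "icp_config")
}

#' Least-squares rigid transform from a vertex pairing
#'
#' The closed-form orthogonal-Procrustes (Kabsch/Horn) solution of the
#' inner ICP step: the rotation + translation (optionally + uniform scale)
#' minimizing the sum of squared residuals between transformed source
#' points and their matched target points. Reflections are excluded
#' (determinant +1).
#'
#' @param pairing a [pair_vertices()] result, or any list with
#'   `source_points` and `closest` n x 3 matrices.
#' @param allow_scale also estimate a uniform scale (default `FALSE`).
#' @return A [rigid_transform].
#' @export
estimate_transform <- function(pairing, allow_scale = FALSE) {
  src <- pairing$source_points
  dst <- pairing$closest
  if (is.null(src) || is.null(dst) || nrow(src) < 3)
    stop("degenerate pairing: need at least 3 point pairs", call. = FALSE)
  cs <- colMeans(src)
  cd <- colMeans(dst)
  src_c <- sweep(src, 2, cs)
  dst_c <- sweep(dst, 2, cd)
  sv <- svd(src_c)$d
  if (sv[2] < 1e-9 * max(sv[1], 1e-300))
    stop("degenerate pairing: points are (nearly) collinear", call. = FALSE)
  H <- crossprod(src_c, dst_c)  # sum of s_i d_i^T
  dec <- svd(H)
  d <- sign(det(dec$v %*% t(dec$u)))
  R <- dec$v %*% diag(c(1, 1, d)) %*% t(dec$u)
  s <- 1
  if (allow_scale) {
    s <- sum(diag(R %*% H)) / sum(src_c^2)
    if (!is.finite(s) || s <= 0) s <- 1
  }
  rigid_transform(rotation = R, translation = cd - s * as.vector(R %*% cs),
                  scale = s)
}

#' Vertex sub-sampling strategies
#'
#' Three ways to reduce the vertex set driving ICP. Random sampling draws
#' `n` vertices uniformly without replacement and is the recommended
#' default — it preserves registration accuracy down to a few hundred
#' samples. Uniform-grid sampling clusters vertices into approximately `n`
#' non-empty cells of a 3D grid (cell edge found by bisection) and draws
#' one random vertex per cell, giving better spatial coverage.
#' Curvature sampling takes the `n` vertices with the largest discrete
#' Gaussian curvature magnitude (angle deficit divided by one third of the
#' incident triangle area; boundary vertices use a half-disc deficit), a
#' deterministic choice concentrated on geometrically salient points.
#'
#' @param m a [trimesh].
#' @param n number of samples; if `n >=` vertex count, all vertices are
#'   returned.
#' @param seed RNG seed (random and uniform-grid strategies).
#' @return Integer vector of vertex indices.
#' @export
subsample_random <- function(m, n, seed = 1L) {
  nv <- n_vertices(m)
  if (n >= nv) return(seq_len(nv))
  sort(with_seed(seed, sample.int(nv, n)))
}

#' @rdname subsample_random
#' @export
subsample_uniform_grid <- function(m, n, seed = 1L) {
  nv <- n_vertices(m)
  if (n >= nv) return(seq_len(nv))
  v <- m$vertices
  lo <- apply(v, 2, min)
  extent <- apply(v, 2, max) - lo
  cell_count <- function(h) {
    key <- paste(floor((v[, 1] - lo[1]) / h), floor((v[, 2] - lo[2]) / h),
                 floor((v[, 3] - lo[3]) / h))
    length(unique(key))
  }
  h_hi <- max(extent, 1e-9) * 2  # one cell
  h_lo <- h_hi / 2
  while (cell_count(h_lo) < n && h_lo > h_hi * 1e-12) h_lo <- h_lo / 2
  # non-empty cell count decreases in h; bisect toward n
  for (i in 1:60) {
    h <- sqrt(h_lo * h_hi)
    cc <- cell_count(h)
    if (abs(cc - n) <= 0.1 * n) break
    if (cc > n) h_lo <- h else h_hi <- h
    h <- sqrt(h_lo * h_hi)
  }
  key <- paste(floor((v[, 1] - lo[1]) / h), floor((v[, 2] - lo[2]) / h),
               floor((v[, 3] - lo[3]) / h))
  groups <- split(seq_len(nv), key)
  picks <- with_seed(seed, vapply(groups, function(g) {
    if (length(g) == 1L) g else g[sample.int(length(g), 1L)]
  }, integer(1)))
  sort(unname(picks))
}

#' @rdname subsample_random
#' @export
subsample_curvature <- function(m, n) {
  k <- gaussian_curvature(m)
  ord <- order(-abs(k), seq_along(k))  # ties broken by vertex index
  sort(head(ord, min(n, length(k))))
}

#' Discrete Gaussian curvature (angle deficit)
#'
#' Per-vertex curvature as the angle deficit — the full angle (2 pi for an
#' interior vertex, pi for a boundary vertex) minus the sum of incident
#' triangle corner angles — normalized by one third of the incident
#' triangle area. Zero on flat interior regions; approximately `1 / r^2`
#' on a sphere of radius `r`.
#'
#' @param m a [trimesh].
#' @return Numeric vector, one curvature per vertex (`NA` for isolated
#'   vertices).
#' @export
gaussian_curvature <- function(m) {
  v <- m$vertices
  f <- m$triangles
  nv <- nrow(v)
  angle_sum <- numeric(nv)
  area_sum <- numeric(nv)
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  area <- 0.5 * sqrt(rowSums(triangle_normals_raw(m)^2))
  corner <- function(p, q, r) {
    u <- q - p
    w <- r - p
    cosang <- rowSums(u * w) /
      pmax(sqrt(rowSums(u^2)) * sqrt(rowSums(w^2)), 1e-300)
    acos(pmin(1, pmax(-1, cosang)))
  }
  angs <- cbind(corner(a, b, c_), corner(b, c_, a), corner(c_, a, b))
  for (k in 1:3) {
    angle_sum <- angle_sum + tapply_sum(angs[, k], f[, k], nv)
    area_sum <- area_sum + tapply_sum(area, f[, k], nv)
  }
  full <- rep(2 * pi, nv)
  be <- boundary_edges(m)
  if (nrow(be) > 0) full[unique(as.vector(be))] <- pi
  out <- (full - angle_sum) / (area_sum / 3)
  out[area_sum <= 0] <- NA_real_
  out
}

#' One-directional ICP registration with auto-cropping
#'
#' Aligns a moving mesh onto a fixed surface by alternating
#' nearest-neighbor pairing and closed-form transform estimation. Each
#' iteration pairs the (sub-sampled) moving vertices with their closest
#' points on the fixed surface, drops ambiguous pairs, and — from the
#' second iteration on, if configured — drops pairs landing on the fixed
#' surface's boundary (auto-cropping, which suppresses the directional
#' asymmetry caused by non-overlapping scan borders). Iteration stops when
#' the mean pairing distance changes by less than `delta_threshold` or
#' after `max_iterations`.
#'
#' @param moving a [trimesh] to be moved.
#' @param fixed a `surface_index` (or [trimesh]) held fixed.
#' @param config an [icp_config()].
#' @return An object of class `icp_result`: `transform` (cumulative
#'   [rigid_transform] mapping the moving mesh's original pose into
#'   alignment), `history` (per-iteration mean pairing distance, mm),
#'   `iterations_run`, `converged`, `sample_indices`, `pairing_stats`.
#' @examples
#' \donttest{
#' shell <- generate_shell(shell_params(resolution = 16, seed = 1))
#' moved <- apply_transform(shell,
#'   rigid_transform(rotation_about_z(0.1), c(2, 0, 0)))
#' fit <- icp_register(moved, shell, icp_config(n_samples = 200))
#' fit$history
#' }
#' @export
icp_register <- function(moving, fixed, config = icp_config()) {
  fixed <- as_surface_index(fixed)
  samples <- switch(config$sampling,
                    random = subsample_random(moving, config$n_samples,
                                              config$seed),
                    uniform_grid = subsample_uniform_grid(
                      moving, config$n_samples, config$seed),
                    curvature = subsample_curvature(moving,
                                                    config$n_samples),
                    none = seq_len(n_vertices(moving)))
  orig <- moving$vertices[samples, , drop = FALSE]
  tf <- identity_transform()
  if (config$init_centroid) {
    tf <- rigid_transform(translation = colMeans(fixed$mesh$vertices) -
                            colMeans(moving$vertices))
  }
  history <- numeric(0)
  converged <- FALSE
  last_pairing <- NULL
  for (it in seq_len(config$max_iterations)) {
    pts <- transform_points(orig, tf)
    crop_now <- it > 1 && config$crop_after_first
    pr <- tryCatch(
      pair_vertices(pts, fixed, crop = crop_now),
      error = function(e)
        stop(sprintf("insufficient overlap at ICP iteration %d: %s", it,
                     conditionMessage(e)), call. = FALSE))
    last_pairing <- pr
    d <- mean(pr$distance)
    history <- c(history, d)
    if (it > 1 && abs(d - history[it - 1]) < config$delta_threshold) {
      converged <- TRUE
      break
    }
    inc <- estimate_transform(pr, allow_scale = config$allow_scale)
    tf <- compose_transforms(inc, tf)
  }
  structure(list(transform = tf, history = history,
                 iterations_run = length(history), converged = converged,
                 sample_indices = samples,
                 pairing_stats = list(
                   n_used = length(last_pairing$distance),
                   n_excluded_tie = last_pairing$n_excluded_tie,
                   n_excluded_crop = last_pairing$n_excluded_crop)),
            class = "icp_result")
}

#' @export
print.icp_result <- function(x, ...) {
  cat(sprintf(
    "icp_result: %d iteration(s), final mean distance %.4f mm (%s)\n",
    x$iterations_run, tail(x$history, 1),
    if (x$converged) "converged" else "max iterations"))
  print(x$transform)
  invisible(x)
}
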