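#' Parameters of a synthetic facial shell
#'
#' Describes an open, bumpy ellipsoid patch — a stand-in for a
#' stereophotogrammetric facial scan: an open shell that wraps around the
#' head the way an ear-to-ear scan does, carries smooth features of a few
#' millimetres to a centimetre (the scale of noses, sockets and lips),
#' and may have holes, a ragged boundary and measurement noise. All
#' lengths in millimetres, angles in degrees.
#'
#' The base surface is the patch of the ellipsoid with semi-axes `radii`
#' spanned by azimuth within `wrap_deg[1]` and elevation within
#' `wrap_deg[2]`. Three distinct semi-axes and a wide wrap leave no
#' rotational near-symmetry and make the surface normals span all
#' directions, which is what makes rigid registration of such shells
#' well-posed.
#'
#' @param resolution vertices per grid side (>= 4).
#' @param radii semi-axes of the underlying ellipsoid (mm, default
#'   `c(75, 85, 95)`).
#' @param wrap_deg angular half-extents `c(azimuth, elevation)` of the
#'   patch in degrees (default `c(75, 55)`, an ear-to-ear,
#'   forehead-to-chin wrap).
#' @param n_bumps number of smooth Gaussian surface features.
#' @param bump_amp feature amplitude (mm, displacement along the outward
#'   normal; sign randomized).
#' @param bump_width feature width (Gaussian sd of the 3D distance
#'   kernel, mm).
#' @param n_holes number of circular holes punched through the shell.
#' @param hole_radius hole radius (mm).
#' @param ragged_amp tangential jitter amplitude of outer-border vertices
#'   (mm), emulating ragged scan trims.
#' @param noise_sd i.i.d. Gaussian vertex noise standard deviation (mm).
#' @param seed RNG seed; generation is fully deterministic per seed.
#' @return A list of class `shell_params`.
#' @export
shell_params <- function(resolution = 32L, radii = c(75, 85, 95),
                         wrap_deg = c(75, 55),
                         n_bumps = 12L, bump_amp = 5, bump_width = 15,
                         n_holes = 0L, hole_radius = 6, ragged_amp = 0,
                         noise_sd = 0, seed = 1L) {
  stopifnot(resolution >= 4, length(radii) == 3, all(radii > 0),
            length(wrap_deg) == 2, all(wrap_deg > 0), all(wrap_deg < 90),
            n_bumps >= 0, bump_amp >= 0, bump_width > 0, n_holes >= 0,
            hole_radius >= 0, ragged_amp >= 0, noise_sd >= 0)
  structure(list(resolution = as.integer(resolution), radii = radii,
                 wrap_deg = wrap_deg, n_bumps = as.integer(n_bumps),
                 bump_amp = bump_amp, bump_width = bump_width,
                 n_holes = as.integer(n_holes), hole_radius = hole_radius,
                 ragged_amp = ragged_amp, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "shell_params")
}

# Regular grid triangulation: two triangles per cell, consistent
# counter-clockwise winding (normals point +z for a flat grid).
grid_triangles <- function(res) {
  ij <- expand.grid(i = seq_len(res - 1), j = seq_len(res - 1))
  v00 <- (ij$j - 1) * res + ij$i
  v10 <- v00 + 1L
  v01 <- v00 + res
  v11 <- v01 + 1L
  rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
}

# Map patch parameters (theta = azimuth, phi = elevation, radians) to the
# ellipsoid surface.
ellipsoid_patch <- function(theta, phi, radii) {
  cbind(radii[1] * sin(theta) * cos(phi),
        radii[2] * sin(phi),
        radii[3] * cos(theta) * cos(phi))
}

#' Generate a synthetic facial shell
#'
#' Builds the shell described by a [shell_params()]: an ellipsoid patch
#' sampled on a regular angular grid, displaced along the outward normal
#' by smooth Gaussian features, with triangles inside hole discs removed,
#' outer-border vertices jittered tangentially, and i.i.d. Gaussian noise
#' added. Unreferenced vertices are compacted away. Deterministic for a
#' fixed seed.
#'
#' @param params a [shell_params()].
#' @return A [trimesh] with at least one boundary loop (one extra loop
#'   per hole).
#' @examples
#' shell <- generate_shell(shell_params(resolution = 12, seed = 3))
#' length(boundary_loops(shell))
#' @export
generate_shell <- function(params) {
  stopifnot(inherits(params, "shell_params"))
  with_seed(params$seed, {
    res <- params$resolution
    tmax <- params$wrap_deg[1] * pi / 180
    pmax_ <- params$wrap_deg[2] * pi / 180
    gu <- seq(-tmax, tmax, length.out = res)
    gw <- seq(-pmax_, pmax_, length.out = res)
    # azimuth varies fastest, matching grid_triangles' vertex order
    theta <- rep(gu, times = res)
    phi <- rep(gw, each = res)
    v <- ellipsoid_patch(theta, phi, params$radii)
    tris <- grid_triangles(res)
    normal_dir <- function(v) {
      n <- cbind(v[, 1] / params$radii[1]^2, v[, 2] / params$radii[2]^2,
                 v[, 3] / params$radii[3]^2)
      n / sqrt(rowSums(n^2))
    }

    # smooth features along the outward normal, 3D Gaussian kernel.
    # Feature centres are drawn in a fixed angular reference frame (not
    # scaled by wrap_deg), so shells generated from the same seed share
    # identical features even when their wrap extents differ — the way
    # two differently trimmed scans of one face share the face.
    ref_t <- 0.85 * 75 * pi / 180
    ref_p <- 0.85 * 55 * pi / 180
    if (params$n_bumps > 0 && params$bump_amp > 0) {
      bc <- ellipsoid_patch(runif(params$n_bumps, -ref_t, ref_t),
                            runif(params$n_bumps, -ref_p, ref_p),
                            params$radii)
      amp <- runif(params$n_bumps, 0.4, 1) * params$bump_amp *
        sample(c(-1, 1), params$n_bumps, replace = TRUE)
      disp <- numeric(nrow(v))
      for (b in seq_len(params$n_bumps)) {
        d2 <- (v[, 1] - bc[b, 1])^2 + (v[, 2] - bc[b, 2])^2 +
          (v[, 3] - bc[b, 3])^2
        disp <- disp + amp[b] * exp(-d2 / (2 * params$bump_width^2))
      }
      v <- v + disp * normal_dir(v)
    }

    # punch holes: drop triangles whose centroid falls inside a sphere
    # around a random surface point
    if (params$n_holes > 0 && params$hole_radius > 0) {
      hc <- ellipsoid_patch(runif(params$n_holes, -0.7 * ref_t,
                                  0.7 * ref_t),
                            runif(params$n_holes, -0.7 * ref_p,
                                  0.7 * ref_p), params$radii)
      cen <- (v[tris[, 1], ] + v[tris[, 2], ] + v[tris[, 3], ]) / 3
      drop <- rep(FALSE, nrow(tris))
      for (h in seq_len(params$n_holes))
        drop <- drop | (rowSums(sweep(cen, 2, hc[h, ])^2) <
                          params$hole_radius^2)
      tris <- tris[!drop, , drop = FALSE]
      if (nrow(tris) == 0)
        stop("degenerate parameters: holes removed all triangles",
             call. = FALSE)
    }

    # ragged outer border: jitter border vertices along the outward
    # tangent (the direction away from the patch centre on the surface)
    if (params$ragged_amp > 0) {
      border <- which(theta <= gu[1] | theta >= gu[res] |
                        phi <= gw[1] | phi >= gw[res])
      inner <- ellipsoid_patch(0.95 * theta[border], 0.95 * phi[border],
                               params$radii)
      tang <- v[border, , drop = FALSE] - inner
      tang <- tang / pmax(sqrt(rowSums(tang^2)), 1e-12)
      v[border, ] <- v[border, ] +
        runif(length(border), -params$ragged_amp, params$ragged_amp) * tang
    }

    if (params$noise_sd > 0)
      v <- v + matrix(rnorm(length(v), sd = params$noise_sd), ncol = 3)

    # compact unreferenced vertices (hole interiors)
    used <- sort(unique(as.vector(tris)))
    remap <- integer(nrow(v))
    remap[used] <- seq_along(used)
    trimesh(v[used, , drop = FALSE],
            matrix(remap[tris], ncol = 3))
  })
}

#' Specification of a synthetic shell population
#'
#' A population shares one base shell shape; each member adds its own
#' smooth shape variation (independent Gaussian features of amplitude
#' `variation_amp` centred at random surface points, giving pairwise
#' distances of a few millimetres, the scale seen between real facial
#' scans) and is displaced by a random rigid transform (rotation up to
#' `max_rotation_deg` about a random axis, translation components uniform
#' within `max_translation`), which is recorded as ground truth.
#'
#' @param n number of faces (>= 2).
#' @param base a [shell_params()] for the shared base shape.
#' @param variation_amp per-face shape-variation amplitude (mm).
#' @param variation_bumps number of per-face variation features.
#' @param variation_width width of variation features (mm).
#' @param max_rotation_deg maximal rigid-jitter rotation (degrees).
#' @param max_translation maximal rigid-jitter translation per axis (mm).
#' @param seed RNG seed.
#' @return A list of class `population_spec`.
#' @export
population_spec <- function(n, base = shell_params(),
                            variation_amp = 4, variation_bumps = 8L,
                            variation_width = 20,
                            max_rotation_deg = 10, max_translation = 10,
                            seed = 1L) {
  stopifnot(n >= 2, variation_amp >= 0, max_rotation_deg >= 0,
            max_translation >= 0)
  structure(list(n = as.integer(n), base = base,
                 variation_amp = variation_amp,
                 variation_bumps = as.integer(variation_bumps),
                 variation_width = variation_width,
                 max_rotation_deg = max_rotation_deg,
                 max_translation = max_translation,
                 seed = as.integer(seed)),
            class = "population_spec")
}

#' Generate a synthetic shell population with ground-truth poses
#'
#' @param spec a [population_spec()].
#' @return A list with `meshes` (list of [trimesh]), `transforms` (the
#'   ground-truth rigid jitter applied to each face), and `base` (the
#'   shared base shell before variation and jitter).
#' @export
generate_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  base <- generate_shell(spec$base)
  meshes <- vector("list", spec$n)
  transforms <- vector("list", spec$n)
  base_normals <- vertex_normals(base)
  base_normals[is.na(base_normals)] <- 0
  for (i in seq_len(spec$n)) {
    shaped <- base
    if (spec$variation_amp > 0 && spec$variation_bumps > 0) {
      shaped <- with_seed(derive_seed(spec$seed, i, 1L), {
        centres <- base$vertices[
          sample.int(n_vertices(base), spec$variation_bumps), ,
          drop = FALSE]
        amp <- runif(spec$variation_bumps, 0.4, 1) * spec$variation_amp *
          sample(c(-1, 1), spec$variation_bumps, replace = TRUE)
        disp <- numeric(n_vertices(base))
        for (b in seq_len(spec$variation_bumps)) {
          d2 <- rowSums(sweep(base$vertices, 2, centres[b, ])^2)
          disp <- disp + amp[b] *
            exp(-d2 / (2 * spec$variation_width^2))
        }
        out <- base
        out$vertices <- base$vertices + disp * base_normals
        out
      })
    }
    tf <- with_seed(derive_seed(spec$seed, i, 2L), {
      if (spec$max_rotation_deg == 0 && spec$max_translation == 0) {
        identity_transform()
      } else {
        axis <- rnorm(3)
        angle <- runif(1, 0, spec$max_rotation_deg * pi / 180)
        rigid_transform(rotation_about_axis(axis, angle),
                        runif(3, -spec$max_translation,
                              spec$max_translation))
      }
    })
    meshes[[i]] <- apply_transform(shaped, tf)
    transforms[[i]] <- tf
  }
  names(meshes) <- sprintf("face_%02d", seq_len(spec$n))
  list(meshes = meshes, transforms = transforms, base = base)
}
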