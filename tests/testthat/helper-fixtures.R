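# Shared fixtures and the independent brute-force nearest-point oracle.

# flat rectangular grid plane in the z = z0 plane, consistent +z winding
make_plane <- function(nx, ny, spacing = 1, z = 0, origin = c(0, 0)) {
  gx <- origin[1] + (seq_len(nx) - 1) * spacing
  gy <- origin[2] + (seq_len(ny) - 1) * spacing
  v <- cbind(rep(gx, times = ny), rep(gy, each = nx), z)
  ij <- expand.grid(i = seq_len(nx - 1), j = seq_len(ny - 1))
  v00 <- (ij$j - 1) * nx + ij$i
  tris <- rbind(cbind(v00, v00 + 1L, v00 + nx + 1L),
                cbind(v00, v00 + nx + 1L, v00 + nx))
  trimesh(v, tris)
}

# closed tetrahedron (no boundary edges)
make_tetrahedron <- function() {
  trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
          rbind(c(1L, 3L, 2L), c(1L, 2L, 4L), c(2L, 3L, 4L),
                c(1L, 4L, 3L)))
}

# Independent exact closest-point-on-triangle: enumerate the seven
# candidate sites (plane projection if inside, three clamped edge
# projections, three vertices) and take the closest. Deliberately a
# different formulation from the packaged query.
oracle_closest_on_tri <- function(p, a, b, c) {
  cands <- list(a, b, c)
  for (e in list(list(a, b), list(b, c), list(c, a))) {
    u <- e[[2]] - e[[1]]
    t <- sum((p - e[[1]]) * u) / sum(u * u)
    t <- min(1, max(0, t))
    cands[[length(cands) + 1]] <- e[[1]] + t * u
  }
  n <- pracma::cross(b - a, c - a)
  nn <- sum(n * n)
  if (nn > 0) {
    q <- p - (sum((p - a) * n) / nn) * n
    # inside test via same-side cross products
    s1 <- sum(pracma::cross(b - a, q - a) * n)
    s2 <- sum(pracma::cross(c - b, q - b) * n)
    s3 <- sum(pracma::cross(a - c, q - c) * n)
    if (s1 >= 0 && s2 >= 0 && s3 >= 0)
      cands[[length(cands) + 1]] <- q
  }
  d2 <- vapply(cands, function(q) sum((p - q)^2), numeric(1))
  cands[[which.min(d2)]]
}

# exhaustive scan over all triangles
oracle_nearest <- function(p, mesh) {
  v <- mesh$vertices
  f <- mesh$triangles
  best <- Inf
  bp <- NULL
  for (t in seq_len(nrow(f))) {
    q <- oracle_closest_on_tri(p, v[f[t, 1], ], v[f[t, 2], ],
                               v[f[t, 3], ])
    d <- sqrt(sum((p - q)^2))
    if (d < best) {
      best <- d
      bp <- q
    }
  }
  list(distance = best, point = bp)
}

# directional mean distance recomputed without the spatial index
oracle_d_avg <- function(fi, fj, crop = FALSE) {
  idx <- build_index(fj)
  hits <- nearest_on_surface(fi$vertices, idx)
  keep <- hits$unique
  if (crop) keep <- keep & !hits$on_boundary
  ds <- vapply(which(keep), function(i)
    oracle_nearest(fi$vertices[i, ], fj)$distance, numeric(1))
  mean(ds)
}

# small memoized shells so expensive fixtures are built once per run
.fx_cache <- new.env(parent = emptyenv())
fx_memo <- function(key, expr) {
  if (!exists(key, envir = .fx_cache))
    assign(key, force(expr), envir = .fx_cache)
  get(key, envir = .fx_cache)
}

fx_shell <- function(res = 20, seed = 2, ...) {
  key <- paste0("shell_", res, "_", seed, "_",
                paste(unlist(list(...)), collapse = "_"))
  fx_memo(key, generate_shell(shell_params(resolution = res, seed = seed,
                                           ...)))
}

rotation_angle <- function(R) {
  acos(min(1, max(-1, (sum(diag(R)) - 1) / 2)))
}
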