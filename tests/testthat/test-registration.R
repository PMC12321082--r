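test_that("transform estimation recovers known rigid motions", {
  set.seed(21)
  pts <- matrix(rnorm(90, sd = 20), ncol = 3)

  # self-pairing: identity
  t0 <- estimate_transform(list(source_points = pts, closest = pts))
  expect_equal(t0$rotation, diag(3), tolerance = 1e-12)
  expect_equal(t0$translation, c(0, 0, 0), tolerance = 1e-12)

  # 15 degrees about z plus a shift
  R <- rotation_about_z(15 * pi / 180)
  dst <- t(R %*% t(pts)) + rep(1, nrow(pts)) %o% c(1, 0, 0)
  tf <- estimate_transform(list(source_points = pts, closest = dst))
  expect_equal(tf$rotation, R, tolerance = 1e-9)
  expect_equal(tf$translation, c(1, 0, 0), tolerance = 1e-9)

  # uniform scale recovered when allowed
  tf2 <- estimate_transform(list(source_points = pts,
                                 closest = 1.3 * dst),
                            allow_scale = TRUE)
  expect_equal(tf2$scale, 1.3, tolerance = 1e-9)

  # degenerate configurations
  col3 <- cbind(1:3, 1:3, 1:3)
  expect_error(estimate_transform(list(source_points = col3,
                                       closest = col3)), "collinear")
  expect_error(estimate_transform(list(source_points = pts[1:2, ],
                                       closest = pts[1:2, ])),
               "at least 3")
})

test_that("random sub-sampling is uniform, exact and reproducible", {
  m <- fx_shell(res = 12)
  nv <- n_vertices(m)
  expect_identical(subsample_random(m, nv + 10), seq_len(nv))
  s1 <- subsample_random(m, 50, seed = 9)
  s2 <- subsample_random(m, 50, seed = 9)
  expect_identical(s1, s2)
  expect_equal(length(unique(s1)), 50)

  # frequency of n = 1 draws is uniform (chi-square)
  plane <- make_plane(5, 4)
  draws <- vapply(1:8000, function(i) subsample_random(plane, 1, seed = i),
                  integer(1))
  tab <- tabulate(draws, nbins = 20)
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)
})

test_that("uniform-grid sub-sampling hits the target cell count", {
  plane <- make_plane(10, 10)
  s <- subsample_uniform_grid(plane, 25, seed = 3)
  expect_true(length(s) >= 22 && length(s) <= 28)
  expect_identical(s, subsample_uniform_grid(plane, 25, seed = 3))
  expect_identical(subsample_uniform_grid(plane, 200, seed = 1),
                   seq_len(100))

  # degenerate spread: all vertices in one tight cluster
  tight <- trimesh(matrix(rnorm(30, sd = 1e-7), ncol = 3) +
                     rep(1, 10) %o% c(5, 5, 5),
                   rbind(c(1L, 2L, 3L)))
  sd_ <- subsample_uniform_grid(tight, 10, seed = 2)
  expect_true(length(sd_) >= 1 && length(sd_) <= 11)
})

test_that("curvature sub-sampling ranks by discrete angle deficit", {
  # flat interior: zero curvature
  plane <- make_plane(8, 8)
  k <- gaussian_curvature(plane)
  be <- unique(as.vector(boundary_edges(plane)))
  interior <- setdiff(seq_len(64), be)
  expect_lt(max(abs(k[interior])), 1e-9)

  # spherical patch: approximately 1 / r^2 away from the boundary
  sph <- generate_shell(shell_params(resolution = 28,
                                     radii = c(80, 80, 80),
                                     n_bumps = 0L, seed = 1))
  ks <- gaussian_curvature(sph)
  bi <- unique(as.vector(boundary_edges(sph)))
  inner <- setdiff(seq_len(n_vertices(sph)), bi)
  expect_lt(max(abs(ks[inner] - 1 / 80^2) / (1 / 80^2)), 0.2)

  # selection equals exhaustive ranking with index tie-break
  shell <- fx_shell(res = 14, n_bumps = 5L, bump_amp = 10,
                    bump_width = 8)
  kk <- gaussian_curvature(shell)
  ord <- order(-abs(kk), seq_along(kk))
  expect_identical(subsample_curvature(shell, 5), sort(ord[1:5]))
})

test_that("ICP aligns a displaced copy back onto the original", {
  shell <- fx_shell(res = 24)
  idx <- build_index(shell)

  # already aligned: converges immediately with near-identity transform
  f0 <- icp_register(shell, idx, icp_config(n_samples = 400, seed = 2))
  expect_equal(f0$iterations_run, 2)
  expect_lt(tail(f0$history, 1), 1e-6)
  expect_lt(rotation_angle(f0$transform$rotation), 1e-9)

  # known-transform recovery, run to convergence
  tf <- rigid_transform(rotation_about_axis(c(0.3, 1, -0.4),
                                            10 * pi / 180), c(3, 1, 2))
  moved <- apply_transform(shell, tf)
  fit <- icp_register(moved, idx,
                      icp_config(n_samples = 1000, seed = 5,
                                 delta_threshold = 1e-6,
                                 max_iterations = 400,
                                 crop_after_first = FALSE))
  reg <- apply_transform(moved, fit$transform)
  expect_lt(mesh_distance(build_index(reg), idx, crop = TRUE), 0.05)
  # composition with the ground truth is near identity
  comp <- compose_transforms(fit$transform, tf)
  expect_lt(rotation_angle(comp$rotation), 1e-3)
  expect_lt(sqrt(sum(comp$translation^2)), 1e-2)

  # deterministic for a fixed seed
  fit2 <- icp_register(moved, idx,
                       icp_config(n_samples = 1000, seed = 5,
                                  delta_threshold = 1e-6,
                                  max_iterations = 400,
                                  crop_after_first = FALSE))
  expect_identical(fit$history, fit2$history)
  expect_identical(fit$transform, fit2$transform)
})

test_that("mean pairing distance is non-increasing once the regime is fixed", {
  shell <- fx_shell(res = 20)
  idx <- build_index(shell)
  moved <- apply_transform(shell, rigid_transform(
    rotation_about_axis(c(1, 0, 1), 6 * pi / 180), c(2, -1, 1)))
  fit <- icp_register(moved, idx,
                      icp_config(n_samples = 600, seed = 3,
                                 delta_threshold = 1e-7,
                                 max_iterations = 80,
                                 crop_after_first = FALSE))
  h <- fit$history
  if (length(h) > 3)
    expect_true(all(diff(h[3:length(h)]) <= 1e-6))
})

test_that("cropping shrinks the registration asymmetry on ragged pairs", {
  asym_gap <- function(seedk, crop) {
    a <- generate_shell(shell_params(resolution = 22,
                                     wrap_deg = c(75, 55),
                                     ragged_amp = 3, seed = seedk))
    b <- generate_shell(shell_params(resolution = 22,
                                     wrap_deg = c(60, 44),
                                     ragged_amp = 3, seed = seedk))
    cfg <- icp_config(n_samples = 600, delta_threshold = 1e-3,
                      max_iterations = 80, crop_after_first = crop,
                      seed = seedk)
    ia <- build_index(a)
    ib <- build_index(b)
    dab <- mesh_distance(build_index(apply_transform(
      a, icp_register(a, ib, cfg)$transform)), ib, crop = crop)
    dba <- mesh_distance(build_index(apply_transform(
      b, icp_register(b, ia, cfg)$transform)), ia, crop = crop)
    abs(dab - dba)
  }
  seeds <- 1:6
  g_crop <- vapply(seeds, asym_gap, numeric(1), crop = TRUE)
  g_nocrop <- vapply(seeds, asym_gap, numeric(1), crop = FALSE)
  # cropped runs are dramatically more symmetric on these fixtures
  expect_lt(mean(g_crop), mean(g_nocrop))
  expect_lt(stats::sd(g_crop), stats::sd(g_nocrop))
})
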