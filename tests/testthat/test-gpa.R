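test_that("average-face update has the right fixed points and centroids", {
  plane <- make_plane(9, 9)

  # population = {template}: fixed point
  up <- update_average_face(plane, list(build_index(plane)), crop = FALSE)
  expect_equal(up$vertices, plane$vertices, tolerance = 1e-12)

  # symmetric offsets cancel
  hi <- make_plane(9, 9, z = 0.5)
  lo <- make_plane(9, 9, z = -0.5)
  up2 <- update_average_face(plane, list(build_index(hi),
                                         build_index(lo)), crop = FALSE)
  expect_equal(up2$vertices, plane$vertices, tolerance = 1e-9)

  # three copies offset +1 mm: average moves +1 mm
  off <- make_plane(9, 9, z = 1)
  io <- build_index(off)
  up3 <- update_average_face(plane, list(io, io, io), crop = FALSE)
  expect_equal(up3$vertices, off$vertices, tolerance = 1e-6)

  # explicit centroid arithmetic: neighbors at +2 and +4
  f2 <- make_plane(9, 9, z = 2)
  f4 <- make_plane(9, 9, z = 4)
  up4 <- update_average_face(plane, list(build_index(f2),
                                         build_index(f4)), crop = FALSE)
  expect_equal(unique(round(up4$vertices[, 3], 9)), 3)
})

test_that("convergence metric is the mutual distance of consecutive averages", {
  a <- make_plane(8, 8)
  b <- make_plane(8, 8, z = 2)
  expect_equal(convergence_metric(a, a), 0)
  expect_equal(convergence_metric(a, b), 2, tolerance = 1e-12)
  s1 <- fx_shell(res = 12, seed = 3)
  s2 <- fx_shell(res = 12, seed = 4, bump_amp = 3)
  expect_identical(convergence_metric(s1, s2),
                   mesh_distance(s1, s2, crop = TRUE))
})

test_that("GPA fixed points: single face and identical copies", {
  shell <- fx_shell(res = 16)
  cfg <- gpa_config(icp = icp_config(n_samples = 400, seed = 2))

  one <- gpa_register(list(shell), cfg)
  expect_equal(one$average_face$vertices, shell$vertices,
               tolerance = 1e-9)

  three <- gpa_register(list(shell, shell, shell), cfg)
  expect_equal(three$iterations_run, 1)
  expect_lt(three$metrics[1], 1e-9)
  expect_equal(three$average_face$vertices, shell$vertices,
               tolerance = 1e-9)
  for (tf in three$transforms)
    expect_lt(rotation_angle(tf$rotation) + sqrt(sum(tf$translation^2)),
              1e-6)
})

test_that("GPA recovers known rigid jitter and tightens the population", {
  pop <- generate_population(population_spec(
    n = 5, base = shell_params(resolution = 20, seed = 11),
    variation_amp = 0, max_rotation_deg = 8, max_translation = 6,
    seed = 19))
  cfg <- gpa_config(icp = icp_config(n_samples = 600,
                                     delta_threshold = 1e-4,
                                     max_iterations = 250,
                                     crop_after_first = FALSE, seed = 3))
  fit <- gpa_register(pop$meshes, cfg)
  expect_true(fit$converged)
  expect_lte(fit$iterations_run, 4)
  reg <- mapply(apply_transform, pop$meshes, fit$transforms,
                SIMPLIFY = FALSE)
  for (i in 1:4)
    expect_lt(mesh_distance(build_index(reg[[i]]),
                            build_index(reg[[i + 1]]), crop = TRUE),
              0.05)
  # the average face reproduces the common shape (template's pose)
  expect_lt(mesh_distance(fit$average_face, pop$meshes[[1]],
                          crop = TRUE), 0.05)
})

test_that("registration reduces pairwise distances in a varied population", {
  pop <- generate_population(population_spec(
    n = 6, base = shell_params(resolution = 20, seed = 11),
    variation_amp = 3, max_rotation_deg = 8, max_translation = 8,
    seed = 23))
  cfg <- gpa_config(icp = icp_config(n_samples = 600,
                                     delta_threshold = 1e-3,
                                     max_iterations = 150, seed = 3))
  fit <- gpa_register(pop$meshes, cfg)
  expect_lte(fit$iterations_run, 5)
  reg <- mapply(apply_transform, pop$meshes, fit$transforms,
                SIMPLIFY = FALSE)
  idx0 <- lapply(pop$meshes, build_index)
  idx1 <- lapply(reg, build_index)
  pre <- post <- c()
  for (i in 1:5) for (j in (i + 1):6) {
    pre <- c(pre, mesh_distance(idx0[[i]], idx0[[j]], crop = TRUE))
    post <- c(post, mesh_distance(idx1[[i]], idx1[[j]], crop = TRUE))
  }
  expect_true(all(post <= pre + 1e-9))
  # distances land in the few-millimetre range of real scan populations
  expect_gt(mean(pre), 0.5)
  expect_lt(mean(post), 6)
})

test_that("population symmetry: average of +delta and -delta is the base", {
  base <- fx_shell(res = 16)
  nrm <- vertex_normals(base)
  delta <- 0.8
  hi <- base
  hi$vertices <- base$vertices + delta * nrm
  lo <- base
  lo$vertices <- base$vertices - delta * nrm
  cfg <- gpa_config(template_index = 1,
                    icp = icp_config(n_samples = 500,
                                     delta_threshold = 1e-5,
                                     max_iterations = 100,
                                     crop_after_first = FALSE, seed = 7))
  # use the base itself as template so the fixed point is the base shape
  fit <- gpa_register(list(base, hi, lo), cfg)
  expect_lt(mesh_distance(fit$average_face, base, crop = TRUE),
            1e-3 * delta + 0.05)
})

test_that("returned transforms reproduce the registered poses exactly", {
  pop <- generate_population(population_spec(
    n = 3, base = shell_params(resolution = 14, seed = 11),
    variation_amp = 2, max_rotation_deg = 5, max_translation = 4,
    seed = 31))
  cfg <- gpa_config(icp = icp_config(n_samples = 300, seed = 3))
  fit <- gpa_register(pop$meshes, cfg)
  expect_length(fit$transforms, 3)
  for (tf in fit$transforms) {
    expect_s3_class(tf, "rigid_transform")
    expect_lt(max(abs(crossprod(tf$rotation) - diag(3))), 1e-9)
  }
})
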