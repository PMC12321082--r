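test_that("cache records match direct per-query recomputation", {
  avg <- fx_shell(res = 12, seed = 3)
  faces <- list(build_index(fx_shell(res = 12, seed = 4, bump_amp = 3)),
                build_index(fx_shell(res = 12, seed = 5, bump_amp = 3)))

  # euclidean cache stores the closest points themselves
  ce <- build_cache(avg, faces, method = "euclidean", crop = TRUE)
  h1 <- nearest_on_surface(avg$vertices, faces[[1]])
  expect_equal(ce$points[[1]], cbind(h1$x, h1$y, h1$z),
               ignore_attr = TRUE)
  expect_identical(ce$valid[, 1], h1$unique & !h1$on_boundary)

  # relative cache stores one signed scalar per record
  cr <- build_cache(avg, faces, method = "relative", crop = TRUE)
  nrm <- vertex_normals(avg)
  r1 <- relative_distance(avg$vertices, nrm, faces[[1]])
  expect_equal(cr$scalars[, 1], r1$value, tolerance = 1e-12)

  # determinism: rebuilt cache is bit-identical
  ce2 <- build_cache(avg, faces, method = "euclidean", crop = TRUE)
  expect_identical(ce$points, ce2$points)
  expect_identical(ce$valid, ce2$valid)

  # gauge against itself: all distances zero
  c0 <- build_cache(avg, list(build_index(avg)), method = "relative",
                    crop = FALSE)
  expect_lt(max(abs(c0$scalars)), 1e-12)
})

test_that("indirect matrix is exact on collinear planar populations", {
  gauge <- make_plane(8, 8, z = 1)
  faces <- lapply(c(0, 1, 2), function(z)
    build_index(make_plane(8, 8, z = z)))
  for (method in c("euclidean", "relative")) {
    dm <- indirect_matrix(build_cache(gauge, faces, method = method,
                                      crop = TRUE))
    expected <- abs(outer(c(0, 1, 2), c(0, 1, 2), "-"))
    expect_equal(unname(dm$matrix), expected, tolerance = 1e-12)
    expect_identical(dm$matrix, t(dm$matrix))
    expect_true(all(diag(dm$matrix) == 0))
  }
})

test_that("indirect matrix equals an index-free brute-force double loop", {
  pop <- generate_population(population_spec(
    n = 4, base = shell_params(resolution = 10, seed = 11),
    variation_amp = 3, max_rotation_deg = 0, max_translation = 0,
    seed = 5))
  avg <- pop$base
  idxs <- lapply(pop$meshes, build_index)
  cache <- build_cache(avg, idxs, method = "euclidean", crop = TRUE)
  dm <- indirect_matrix(cache)

  # brute force: per pair, recompute every per-vertex measure
  hits <- lapply(pop$meshes, function(f) {
    t(vapply(seq_len(n_vertices(avg)), function(i) {
      o <- oracle_nearest(avg$vertices[i, ], f)
      o$point
    }, numeric(3)))
  })
  hh <- lapply(idxs, function(ii) nearest_on_surface(avg$vertices, ii))
  for (i in 1:3) for (j in (i + 1):4) {
    jv <- (hh[[i]]$unique & !hh[[i]]$on_boundary) &
      (hh[[j]]$unique & !hh[[j]]$on_boundary)
    ref <- mean(sqrt(rowSums((hits[[i]][jv, ] - hits[[j]][jv, ])^2)))
    expect_equal(dm$matrix[i, j], ref, tolerance = 1e-9)
  }
})

test_that("identical registered copies give an all-zero matrix", {
  shell <- fx_shell(res = 12)
  idx <- build_index(shell)
  dm <- indirect_matrix(build_cache(shell, list(idx, idx, idx),
                                    method = "relative", crop = TRUE))
  expect_true(all(abs(dm$matrix) < 1e-12))
  fr <- direct_matrix(list(shell, shell, shell), mode = "FR")
  expect_true(all(abs(fr$matrix) < 1e-12))
})

test_that("the BL baseline registers pairs bidirectionally", {
  a <- fx_shell(res = 16, seed = 6)
  b <- apply_transform(a, rigid_transform(
    rotation_about_axis(c(0, 1, 0.2), 4 * pi / 180), c(2, 1, -1)))
  bl <- direct_matrix(list(a, b), mode = "BL",
                      icp = icp_config(sampling = "none",
                                       delta_threshold = 1e-5,
                                       max_iterations = 200,
                                       crop_after_first = FALSE))
  expect_lt(bl$matrix[1, 2], 0.05)
  expect_identical(bl$matrix[1, 2], bl$matrix[2, 1])
})

test_that("euclidean and relative caches agree on smooth populations", {
  pop <- generate_population(population_spec(
    n = 5, base = shell_params(resolution = 16, seed = 11),
    variation_amp = 3, max_rotation_deg = 0, max_translation = 0,
    seed = 9))
  idxs <- lapply(pop$meshes, build_index)
  me <- indirect_matrix(build_cache(pop$base, idxs,
                                    method = "euclidean"))$matrix
  mr <- indirect_matrix(build_cache(pop$base, idxs,
                                    method = "relative"))$matrix
  ut <- upper.tri(me)
  expect_lt(mean(abs(me[ut] - mr[ut])), 0.1 * mean(me[ut]))
})

test_that("CSV export writes symmetric matrices with empty missing cells", {
  m <- matrix(c(0, 1.5, NA, 1.5, 0, 2.5, NA, 2.5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  dm <- structure(list(matrix = m, counts = matrix(5L, 3, 3),
                       method = "relative"), class = "distance_matrix")
  p <- withr::local_tempfile(fileext = ".csv")
  write_distance_csv(dm, p, long = TRUE)
  txt <- readLines(p)
  expect_equal(txt[1], "face,a,b,c")
  expect_match(txt[2], "^a,0,1\\.5,$")  # NA serialized as empty, not 0
  back <- read.csv(p, row.names = 1)
  expect_equal(unname(as.matrix(back)), unname(m))
  expect_true(file.exists(sub("\\.csv$", "_long.csv", p)))
})
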