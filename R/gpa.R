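#' GPA configuration
#'
#' Settings for the batch (N:N) registration loop: which face seeds the
#' template, the convergence threshold on the change between consecutive
#' average faces, the iteration cap, and the ICP settings used for every
#' per-face registration.
#'
#' @param template_index index of the face cloned as the initial template
#'   (default 1; the choice is the analyst's and mildly affects the final
#'   average).
#' @param psm_threshold convergence threshold on the surface distance
#'   between consecutive average faces (default 0.3).
#' @param max_gpa_iterations iteration cap (default 10; three are usually
#'   sufficient).
#' @param icp an [icp_config()] for the per-face registrations.
#' @return A list of class `gpa_config`.
#' @export
gpa_config <- function(template_index = 1L, psm_threshold = 0.3,
                       max_gpa_iterations = 10L, icp = icp_config()) {
  stopifnot(psm_threshold > 0, max_gpa_iterations >= 1,
            template_index >= 1)
  structure(list(template_index = as.integer(template_index),
                 psm_threshold = psm_threshold,
                 max_gpa_iterations = as.integer(max_gpa_iterations),
                 icp = icp),
            class = "gpa_config")
}

#' Transmute a template mesh toward the population average
#'
#' Every template vertex is displaced by the mean of the vectors to its
#' nearest neighbors across the population: `v + mean(near(v, f) - v)`
#' over the usable faces, i.e. the vertex moves toward the centroid of its
#' nearest neighbors. A face is unusable for a vertex when the nearest
#' neighbor is ambiguous (multiple nearest neighbors) or, under cropping,
#' lies on that face's boundary. Vertices with no usable face are left
#' unchanged and flagged. Topology is preserved; vertex normals are
#' recomputed (the relative indirect measure needs them).
#'
#' @param template a [trimesh] (current template/average face).
#' @param faces list of `surface_index`es (or meshes), registered into the
#'   template's frame.
#' @param crop skip boundary-landing neighbors (default `TRUE`).
#' @return The updated [trimesh], with attribute `unusable`: indices of
#'   vertices left unchanged.
#' @export
update_average_face <- function(template, faces, crop = TRUE) {
  v <- template$vertices
  nv <- nrow(v)
  acc <- matrix(0, nv, 3)
  cnt <- numeric(nv)
  for (f in faces) {
    hits <- nearest_on_surface(v, f)
    ok <- hits$unique
    if (crop) ok <- ok & !hits$on_boundary
    acc[ok, 1] <- acc[ok, 1] + (hits$x[ok] - v[ok, 1])
    acc[ok, 2] <- acc[ok, 2] + (hits$y[ok] - v[ok, 2])
    acc[ok, 3] <- acc[ok, 3] + (hits$z[ok] - v[ok, 3])
    cnt <- cnt + ok
  }
  unusable <- which(cnt == 0)
  if (length(unusable) > nv / 2)
    stop("degenerate population: over half of the template vertices have ",
         "no usable nearest neighbor", call. = FALSE)
  scale <- ifelse(cnt > 0, 1 / pmax(cnt, 1), 0)
  out <- template
  out$vertices <- v + acc * scale
  out$normals <- vertex_normals(out)
  attr(out$normals, "isolated") <- NULL
  attr(out, "unusable") <- unusable
  out
}

#' Convergence metric between consecutive average faces
#'
#' The mutual surface distance ([mesh_distance()]) between the previous
#' and the updated average face; the GPA loop terminates when this change
#' falls below the configured threshold. Used as a surrogate for a
#' Procrustes surface metric on the same pair.
#'
#' @param prev_avg,new_avg [trimesh] objects of identical topology.
#' @return Non-negative scalar (mm).
#' @export
convergence_metric <- function(prev_avg, new_avg) {
  mesh_distance(prev_avg, new_avg, crop = TRUE)
}

#' Batch (N:N) registration via generalized Procrustes analysis with ICP
#'
#' Registers a population of open shell meshes into a common frame without
#' landmarks. A template face is cloned and then repeatedly (1) used as
#' the fixed target for a one-directional ICP registration of every face,
#' and (2) transmuted toward the population average by moving each vertex
#' to the centroid of its nearest neighbors across the registered faces
#' ([update_average_face()]). The loop stops when consecutive average
#' faces differ by less than `psm_threshold` ([convergence_metric()]) or
#' after `max_gpa_iterations`. Cost per iteration is linear in the number
#' of faces.
#'
#' Faces whose registration fails for insufficient overlap are excluded
#' (permanently) with a warning; the run continues while at least two
#' faces remain.
#'
#' @param faces list of [trimesh] objects, roughly pre-aligned.
#' @param config a [gpa_config()].
#' @return An object of class `gpa_result`: `average_face` (a [trimesh]
#'   with the template's topology and recomputed normals), `transforms`
#'   (one cumulative [rigid_transform] per input face, mapping its
#'   original pose into the common frame), `metrics` (per-iteration
#'   convergence values), `iterations_run`, `converged`, `included`
#'   (logical per face).
#' @examples
#' \donttest{
#' pop <- generate_population(population_spec(
#'   n = 4, base = shell_params(resolution = 16),
#'   variation_amp = 0, max_rotation_deg = 5, max_translation = 3,
#'   seed = 7))
#' fit <- gpa_register(pop$meshes, gpa_config(icp = icp_config(
#'   n_samples = 200)))
#' fit$metrics
#' }
#' @export
gpa_register <- function(faces, config = gpa_config()) {
  n <- length(faces)
  if (n < 1) stop("need at least one face", call. = FALSE)
  if (config$template_index > n)
    stop("template_index out of range", call. = FALSE)
  avg <- faces[[config$template_index]]  # Step 1: clone the template
  posed <- faces
  transforms <- replicate(n, identity_transform(), simplify = FALSE)
  included <- rep(TRUE, n)
  metrics <- numeric(0)
  converged <- FALSE
  crop <- config$icp$crop_after_first
  for (g in seq_len(config$max_gpa_iterations)) {
    avg_index <- build_index(avg)
    # Step 2: one-directional ICP of every face onto the current average
    for (i in seq_len(n)) {
      if (!included[i]) next
      icp_i <- config$icp
      icp_i$seed <- derive_seed(config$icp$seed, i, g)
      res <- tryCatch(icp_register(posed[[i]], avg_index, icp_i),
                      error = function(e) e)
      if (inherits(res, "error")) {
        warning(sprintf("face %d excluded in GPA iteration %d: %s", i, g,
                        conditionMessage(res)), call. = FALSE)
        included[i] <- FALSE
        next
      }
      transforms[[i]] <- compose_transforms(res$transform, transforms[[i]])
      posed[[i]] <- apply_transform(posed[[i]], res$transform)
    }
    if (sum(included) < 1 || (n >= 2 && sum(included) < 2))
      stop("too few faces left for averaging", call. = FALSE)
    # Step 3: transmute the template toward the centroid of neighbors
    face_indices <- lapply(posed[included], build_index)
    new_avg <- update_average_face(avg, face_indices, crop = crop)
    # Step 4: stop when the average face stabilizes
    metric <- convergence_metric(avg, new_avg)
    metrics <- c(metrics, metric)
    avg <- new_avg
    if (metric < config$psm_threshold) {
      converged <- TRUE
      break
    }
  }
  structure(list(average_face = avg, transforms = transforms,
                 metrics = metrics, iterations_run = length(metrics),
                 converged = converged, included = included),
            class = "gpa_result")
}

#' @export
print.gpa_result <- function(x, ...) {
  cat(sprintf(
    "gpa_result: %d face(s), %d iteration(s), final metric %.4f mm (%s)\n",
    length(x$transforms), x$iterations_run, tail(x$metrics, 1),
    if (x$converged) "converged" else "max iterations"))
  if (!all(x$included))
    cat(sprintf("  excluded faces: %s\n",
                paste(which(!x$included), collapse = ", ")))
  invisible(x)
}
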