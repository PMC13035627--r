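#' Define a synthetic elasticity phantom
#'
#' A rectangular volume of homogeneous background gel with embedded stiff
#' inclusions (spheres or axis-aligned ellipsoids), mirroring gelatin
#' calibration phantoms: stiff spherical inclusions (radius 7.5 mm,
#' E = 19.8 kPa) embedded in a 7.9 kPa background cube. A single Poisson's
#' ratio is shared by all components (nearly incompressible gels; the
#' default 0.45 keeps full-integration hexahedra out of the locking regime).
#'
#' @param extent length-3 volume (mm).
#' @param background_E background Young's modulus (kPa).
#' @param inclusions list of inclusions, each
#'   `list(shape = "sphere"|"ellipsoid", center = mm 3-vector, radii = mm
#'   (scalar for spheres), E = kPa)`.
#' @param nu Poisson's ratio in (0, 0.5), shared.
#' @return a `phantom_spec`.
#' @export
phantom_spec <- function(extent, background_E, inclusions = list(), nu = 0.45) {
  extent <- as.numeric(extent)
  stopifnot(length(extent) == 3, all(extent > 0), background_E > 0,
            nu > 0, nu < 0.5)
  inclusions <- lapply(inclusions, function(inc) {
    inc$shape <- match.arg(inc$shape, c("sphere", "ellipsoid"))
    inc$center <- as.numeric(inc$center)
    inc$radii <- rep(as.numeric(inc$radii), length.out = 3)
    if (inc$E <= 0) stop("inclusion modulus must be positive")
    if (any(inc$center - inc$radii < 0) || any(inc$center + inc$radii > extent))
      stop("inclusion extends outside the phantom volume")
    inc
  })
  structure(list(extent = extent, background_E = background_E,
                 inclusions = inclusions, nu = nu), class = "phantom_spec")
}

#' True modulus field of a phantom
#'
#' @param phantom a `phantom_spec`.
#' @param x positions: an `autop_mesh` (its integration points are used) or
#'   an n x 3 matrix (mm).
#' @return Young's modulus E (kPa) at each position.
#' @export
material_field <- function(phantom, x) {
  if (inherits(x, "autop_mesh")) x <- x$ip_coords
  x <- rbind(x)
  E <- rep(phantom$background_E, nrow(x))
  for (inc in phantom$inclusions) {
    d2 <- sweep(x, 2, inc$center)
    d2 <- sweep(d2, 2, inc$radii, "/")
    E[rowSums(d2^2) <= 1] <- inc$E
  }
  E
}

#' Solver material carrying the true phantom stiffness
#' @inheritParams material_field
#' @param mesh an `autop_mesh`.
#' @export
phantom_material <- function(phantom, mesh) {
  material_scaled(iso_stiffness(1, phantom$nu), material_field(phantom, mesh))
}

#' Forward-simulate one compression plane
#'
#' Presses a rigid flat probe of the given footprint into the top surface in
#' displacement-controlled load steps, solving with the true phantom
#' stiffness. For each step it records the cumulative probe displacement
#' `u`, the total axial reaction force `f` (N, positive in compression) and
#' the exact axial (y) nodal displacements at all mesh nodes within the
#' measurement slab (scan plane +- half an element, across the footprint
#' length and the full depth). The probe footprint is clipped to the top
#' surface when it overhangs the phantom.
#'
#' @param phantom a `phantom_spec`.
#' @param mesh an `autop_mesh` spanning the phantom extent.
#' @param pose list with `center_z` (mm, scan-plane position; plane normal is
#'   z) and optionally `center_x`; see [footprint_nodes()].
#' @param protocol list with `n_steps` (default 3) and `step_mm` (default
#'   0.5, probe travel per load step).
#' @param footprint list with `length_mm` (default 46) and `width_mm`
#'   (default 11).
#' @param full_field record all three displacement components at every mesh
#'   node instead of axial displacements in the scan slab. This
#'   ideal-information mode has no experimental analog; it bounds what the
#'   method can achieve when displacement information is complete.
#' @return a `plane_measurements` object with this single plane.
#' @export
simulate_plane <- function(phantom, mesh, pose,
                           protocol = list(n_steps = 3, step_mm = 0.5),
                           footprint = list(length_mm = 46, width_mm = 11),
                           full_field = FALSE) {
  stopifnot(inherits(phantom, "phantom_spec"), inherits(mesh, "autop_mesh"))
  if (any(abs(mesh$extent - phantom$extent) > 1e-9))
    stop("mesh extent does not match the phantom")
  cz <- pose$center_z
  cx <- if (is.null(pose$center_x)) mesh$extent[1] / 2 else pose$center_x
  if (cz < 0 || cz > mesh$extent[3]) stop("compression-plane pose is off the surface")
  fp <- footprint_nodes(mesh, center_z = cz, center_x = cx,
                        length_mm = footprint$length_mm, width_mm = footprint$width_mm)
  meas_nodes <- if (full_field) seq_len(mesh$n_nodes) else
    slab_nodes(mesh, center_z = cz, center_x = cx, length_mm = footprint$length_mm)
  bot <- mesh_face_nodes(mesh, "ymin")
  mat <- phantom_material(phantom, mesh)
  steps <- vector("list", protocol$n_steps)
  for (k in seq_len(protocol$n_steps)) {
    u_k <- k * protocol$step_mm
    fixed <- rbind(
      data.frame(node = rep(bot, each = 3), axis = rep(1:3, length(bot)), value = 0),
      data.frame(node = fp, axis = 2, value = -u_k))
    sol <- fem_solve(mesh, mat, bc_set(fixed = fixed, footprint = fp))
    steps[[k]] <- c(list(u = u_k, f = -sol$reaction_force,
                         uy = sol$u[meas_nodes, 2]),
                    if (full_field) list(u3 = sol$u[meas_nodes, , drop = FALSE]))
  }
  plane <- list(plane_id = sprintf("z%g", cz),
                pose = list(center_z = cz, center_x = cx, normal_axis = "z",
                            footprint = footprint, full_field = full_field),
                footprint_nodes = fp, measured_nodes = meas_nodes,
                steps = steps)
  structure(list(mesh_spec = list(extent = mesh$extent, element_size = mesh$h),
                 planes = list(plane)),
            class = "plane_measurements")
}

#' Combine measurement sets acquired on the same mesh
#' @param ... `plane_measurements` objects.
#' @export
combine_measurements <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) && !inherits(sets[[1]], "plane_measurements"))
    sets <- sets[[1]]
  base <- sets[[1]]
  for (s in sets[-1]) {
    if (!isTRUE(all.equal(s$mesh_spec, base$mesh_spec)))
      stop("measurement sets were acquired on different meshes")
    base$planes <- c(base$planes, s$planes)
  }
  base
}

#' @export
print.plane_measurements <- function(x, ...) {
  cat(sprintf("<plane_measurements> %d plane(s) on a %s mm mesh (h = %g mm)\n",
              length(x$planes), paste(x$mesh_spec$extent, collapse = "x"),
              x$mesh_spec$element_size))
  for (p in x$planes)
    cat(sprintf("  %s: %d steps, %d footprint nodes, %d measured nodes\n",
                p$plane_id, length(p$steps), length(p$footprint_nodes),
                length(p$measured_nodes)))
  invisible(x)
}

#' Read / write phantom specifications as YAML
#'
#' @param phantom a `phantom_spec`.
#' @param path file path (`.yaml`).
#' @export
phantom_save_yaml <- function(phantom, path) {
  stopifnot(inherits(phantom, "phantom_spec"))
  yaml::write_yaml(list(
    extent = phantom$extent, background_E = phantom$background_E,
    poisson_ratio = phantom$nu,
    inclusions = lapply(phantom$inclusions, function(i)
      list(shape = i$shape, center = i$center, radii = i$radii, E = i$E))), path)
  invisible(path)
}

#' @rdname phantom_save_yaml
#' @export
phantom_load_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  phantom_spec(unlist(y$extent), y$background_E,
               inclusions = y$inclusions %||% list(),
               nu = y$poisson_ratio %||% 0.45)
}

#' Displacement error model
#'
#' Speckle-tracking displacement errors behave as a smooth, spatially
#' uniform bias rather than white variance; the model adds
#' `bias_amplitude * pattern(x)` plus optional seeded white noise to the
#' measured axial displacements only (`f` and `u` untouched).
#'
#' @param bias_amplitude bias amplitude (mm).
#' @param bias_pattern `"uniform"` (constant 1) or `"linear"` (low-order
#'   ramp across depth, range 0.5..1).
#' @param noise_sd white-noise standard deviation (mm).
#' @param seed integer seed; corruption is reproducible.
#' @export
error_model <- function(bias_amplitude = 0, bias_pattern = c("uniform", "linear"),
                        noise_sd = 0, seed = 1L) {
  stopifnot(bias_amplitude >= 0, noise_sd >= 0)
  structure(list(bias_amplitude = bias_amplitude,
                 bias_pattern = match.arg(bias_pattern),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "autop_error_model")
}

#' Corrupt measured displacements
#'
#' @param meas a `plane_measurements`.
#' @param model an [error_model()].
#' @param mesh the mesh the measurements live on (needed for the spatial
#'   bias pattern).
#' @export
corrupt <- function(meas, model, mesh) {
  stopifnot(inherits(meas, "plane_measurements"), inherits(model, "autop_error_model"))
  if (model$bias_amplitude == 0 && model$noise_sd == 0) return(meas)
  rng <- rng_stream(model$seed)
  for (i in seq_along(meas$planes)) {
    p <- meas$planes[[i]]
    xs <- mesh$nodes[p$measured_nodes, , drop = FALSE]
    pat <- switch(model$bias_pattern,
                  uniform = rep(1, nrow(xs)),
                  linear = 0.5 + 0.5 * xs[, 2] / mesh$extent[2])
    for (k in seq_along(p$steps)) {
      uy <- p$steps[[k]]$uy
      uy <- uy + model$bias_amplitude * pat
      if (model$noise_sd > 0)
        uy <- uy + rng$norm(length(uy), model$noise_sd)
      p$steps[[k]]$uy <- uy
    }
    meas$planes[[i]] <- p
  }
  meas
}

#' Canned phantom/measurement configurations
#'
#' Named reduced- and full-scale study set-ups:
#' \describe{
#'   \item{`two_sphere_full`}{50 mm cube, 2-mm mesh, two 7.5 mm-radius
#'     19.8 kPa spheres in 7.9 kPa background, seven parallel compression
#'     planes 4 mm apart.}
#'   \item{`two_sphere_desk`}{reduced 32 mm cube, 4-mm mesh, same materials,
#'     3 parallel planes 4 mm apart passing through the sphere centres.}
#'   \item{`homogeneous_desk`}{32 mm cube, 4-mm mesh, homogeneous 7.9 kPa,
#'     one central plane.}
#' }
#'
#' @param name fixture name.
#' @return list with `phantom`, `element_size`, `poses` (list of plane
#'   poses), `protocol` and `footprint`.
#' @export
standard_fixtures <- function(name) {
  fixtures <- list(
    two_sphere_full = function() list(
      phantom = phantom_spec(c(50, 50, 50), 7.9, list(
        list(shape = "sphere", center = c(17, 25, 19), radii = 7.5, E = 19.8),
        list(shape = "sphere", center = c(33, 25, 31), radii = 7.5, E = 19.8))),
      element_size = 2,
      poses = lapply(seq(13, 37, by = 4), function(z) list(center_z = z)),
      protocol = list(n_steps = 3, step_mm = 0.5),
      footprint = list(length_mm = 46, width_mm = 11)),
    two_sphere_desk = function() list(
      phantom = phantom_spec(c(32, 32, 32), 7.9, list(
        list(shape = "sphere", center = c(11, 16, 12), radii = 7.5, E = 19.8),
        list(shape = "sphere", center = c(21, 16, 20), radii = 7.5, E = 19.8))),
      element_size = 4,
      poses = lapply(c(12, 16, 20), function(z) list(center_z = z)),
      protocol = list(n_steps = 3, step_mm = 0.5),
      footprint = list(length_mm = 46, width_mm = 11)),
    homogeneous_desk = function() list(
      phantom = phantom_spec(c(32, 32, 32), 7.9),
      element_size = 4,
      poses = list(list(center_z = 16)),
      protocol = list(n_steps = 3, step_mm = 0.5),
      footprint = list(length_mm = 46, width_mm = 11))
  )
  if (!name %in% names(fixtures))
    stop(sprintf("unknown fixture '%s'; available: %s", name,
                 paste(names(fixtures), collapse = ", ")))
  fixtures[[name]]()
}

#' Simulate every plane of a fixture
#'
#' Convenience wrapper: builds the mesh and forward-simulates all
#' compression planes of a [standard_fixtures()] entry (or any list of the
#' same shape).
#'
#' @param fx a fixture list.
#' @return list with `mesh`, `phantom` and `measurements`.
#' @export
simulate_fixture <- function(fx) {
  mesh <- build_hex_mesh(fx$phantom$extent, fx$element_size)
  sets <- lapply(fx$poses, function(pose)
    simulate_plane(fx$phantom, mesh, pose, fx$protocol, fx$footprint))
  list(mesh = mesh, phantom = fx$phantom,
       measurements = combine_measurements(sets))
}
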