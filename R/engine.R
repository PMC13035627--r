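# AutoP engine: dual FEA per compression plane, training-field assembly,
# spatial subsampling and weighting.

plane_by_index <- function(meas, idx) {
  if (idx < 1 || idx > length(meas$planes)) stop("no such plane: ", idx)
  meas$planes[[idx]]
}

bottom_fixed <- function(mesh) {
  bot <- mesh_face_nodes(mesh, "ymin")
  data.frame(node = rep(bot, each = 3), axis = rep(1:3, length(bot)), value = 0)
}

#' Force-driven FEA for one plane and load step
#'
#' Applies the measured total force through the rigid probe footprint
#' (axial dofs tied, total force on the tie), fixes the bottom surface
#' (no-slip) and solves with the current CaNNCM tangent stiffness. Yields
#' the stress field used as training targets plus the strains this solve
#' produced (needed by the strain-reversibility statistic).
#'
#' @param mesh an `autop_mesh`.
#' @param model a `cannccm`.
#' @param meas a `plane_measurements`.
#' @param plane_index,step_index which recorded plane / load step.
#' @return an `autop_solution` (stress kPa, strain, reaction N).
#' @export
run_fea_sigma <- function(mesh, model, meas, plane_index, step_index) {
  p <- plane_by_index(meas, plane_index)
  if (step_index < 1 || step_index > length(p$steps)) stop("no such load step")
  f <- p$steps[[step_index]]$f
  bcs <- bc_set(fixed = bottom_fixed(mesh), footprint = p$footprint_nodes,
                footprint_force = -f)
  fem_solve(mesh, cannccm_material(model, mesh), bcs)
}

#' Displacement-driven FEA for one plane and load step
#'
#' Prescribes the measured axial displacements at all in-plane measurement
#' nodes and the probe displacement on the footprint, fixes the bottom
#' surface, and solves the remaining dofs with the current CaNNCM. The
#' returned strain field provides the strain half of the training pairs.
#'
#' @inheritParams run_fea_sigma
#' @export
run_fea_epsilon <- function(mesh, model, meas, plane_index, step_index) {
  p <- plane_by_index(meas, plane_index)
  if (step_index < 1 || step_index > length(p$steps)) stop("no such load step")
  st <- p$steps[[step_index]]
  fp <- p$footprint_nodes
  keep <- !(p$measured_nodes %in% fp)
  meas_fix <- if (isTRUE(p$pose$full_field) && !is.null(st$u3)) {
    mn <- p$measured_nodes[keep]
    data.frame(node = rep(mn, 3), axis = rep(1:3, each = length(mn)),
               value = as.vector(st$u3[keep, ]))
  } else {
    data.frame(node = p$measured_nodes[keep], axis = 2, value = st$uy[keep])
  }
  fixed <- rbind(
    bottom_fixed(mesh),
    data.frame(node = fp, axis = 2, value = -st$u),
    meas_fix)
  # drop duplicates with the bottom fixture (slab nodes on the bottom face)
  dof <- 3L * (fixed$node - 1L) + fixed$axis
  fixed <- fixed[!duplicated(dof), , drop = FALSE]
  fem_solve(mesh, cannccm_material(model, mesh), bc_set(fixed = fixed, footprint = fp))
}

#' Assemble a training field from a dual-FEA pair
#'
#' One record per integration point: position, stress from the force-driven
#' solve, strain from the displacement-driven solve, and the strains the
#' force-driven solve produced; plus a selection mask and weights (all
#' selected, unit weight, until [subsample()] / [spatial_weight()] are
#' applied).
#'
#' @param mesh an `autop_mesh`.
#' @param sol_sigma,sol_epsilon solutions from [run_fea_sigma()] and
#'   [run_fea_epsilon()].
#' @param plane_id,step_index identifiers for alignment across passes.
#' @return a `training_field`.
#' @export
training_field <- function(mesh, sol_sigma, sol_epsilon, plane_id, step_index) {
  stopifnot(nrow(sol_sigma$stress) == mesh$n_ip,
            nrow(sol_epsilon$strain) == mesh$n_ip)
  structure(list(plane_id = plane_id, step_index = step_index,
                 x = mesh$ip_coords,
                 sigma = sol_sigma$stress,
                 eps = sol_epsilon$strain,
                 eps_force = sol_sigma$strain,
                 mask = rep(TRUE, mesh$n_ip),
                 weight = rep(1, mesh$n_ip)),
            class = "training_field")
}

#' Tidy a training field
#' @param x a `training_field`.
#' @param ... unused.
#' @export
tidy.training_field <- function(x, ...) {
  tibble::as_tibble(data.frame(
    plane_id = x$plane_id, step = x$step_index,
    x = x$x[, 1], y = x$x[, 2], z = x$x[, 3],
    setNames(as.data.frame(x$sigma), paste0("sig_", voigt_labels())),
    setNames(as.data.frame(x$eps), paste0("eps_", voigt_labels())),
    mask = x$mask, weight = x$weight))
}

plane_distance <- function(x, pose) {
  # distance from points to the scan plane (normal axis z)
  abs(x[, 3] - pose$center_z)
}

#' Spatially subsample a training field
#'
#' Keeps every integration point within `near_distance` of the measurement
#' plane; outside that region, a seeded random `floor(fraction * n)` points
#' are selected. Subsampling discards; it never reweights.
#'
#' @param field a `training_field`.
#' @param pose the plane pose (`list(center_z = ...)`).
#' @param near_distance near-plane distance (mm); accuracy is best within
#'   2-3 mm of a compression plane, so the default is 3.
#' @param fraction selection fraction outside the near region, in (0, 1].
#' @param seed integer seed making the selection reproducible.
#' @export
subsample <- function(field, pose, near_distance = 3, fraction = 0.1, seed = 1L) {
  if (near_distance < 0) stop("`near_distance` must be nonnegative")
  if (fraction <= 0 || fraction > 1) stop("`fraction` must be in (0, 1]")
  d <- plane_distance(field$x, pose)
  near <- d <= near_distance + 1e-9
  mask <- near
  out_idx <- which(!near)
  if (length(out_idx) && fraction < 1) {
    n_pick <- floor(fraction * length(out_idx))
    rng <- rng_stream(seed)
    if (n_pick > 0) mask[rng$sample(out_idx, n_pick)] <- TRUE
  } else {
    mask[out_idx] <- TRUE
  }
  field$mask <- mask
  field
}

#' Spatial weight of a training point
#'
#' Gaussian-shaped emphasis on points near the measurement plane:
#' `w(d) = floor + (1 - floor) * exp(-d^2 / (2 s^2))` with `s =
#' near_distance`. Weighting retains but adjusts the influence of all
#' remaining training data: w(0) = 1, monotonically nonincreasing, with a
#' strictly positive asymptote.
#'
#' @param d distance(s) to the measurement plane (mm).
#' @param near_distance scale of the emphasis region (mm).
#' @param floor asymptotic weight at large distance, in (0, 1).
#' @export
spatial_weight <- function(d, near_distance = 3, floor = 0.1) {
  stopifnot(floor > 0, floor < 1, near_distance > 0)
  floor + (1 - floor) * exp(-d^2 / (2 * near_distance^2))
}

apply_focus <- function(field, pose, opts, do_subsample, seed) {
  if (do_subsample)
    field <- subsample(field, pose, opts$near_distance, opts$subsample_fraction, seed)
  field$weight <- spatial_weight(plane_distance(field$x, pose),
                                 opts$near_distance, opts$weight_floor)
  field
}

#' Engine options
#'
#' @param near_distance mm; near-plane region for subsampling/weighting.
#' @param subsample_fraction fraction of far-field points kept in training
#'   for multi-plane models.
#' @param weight_floor asymptotic spatial weight.
#' @param mpn_control,sn_control optimizer settings ([train_control()]); the
#'   MPN phase targets the lax criterion (20% relative RMS stress error),
#'   SN phases the stringent one (2%).
#' @param window_planes,window_retention,window_weight training-data history
#'   window: how many previously introduced planes to mix in, the random
#'   retention fraction of their points, and the weight multiplier.
#' @param sn_relax under-relaxation factors for SN updates, in (0, 1]:
#'   `c(individual, joint)`. Each cycle the SN is trained toward
#'   `(1 - a) * sigma_model + a * sigma_data` where `sigma_model` is the
#'   model's own stress response before the update. The dual-FEA iteration
#'   is a fixed-point map; away from a measured plane its strain data are
#'   partly model-determined, so single-plane (introduction) cycles have
#'   near-unit gain and need strong damping, while joint all-plane cycles
#'   are contractive and tolerate larger steps. 1 disables damping.
#' @param entropy_bins histogram bins for the per-pass statistics.
#' @export
autop_options <- function(near_distance = 3, subsample_fraction = 0.1,
                          weight_floor = 0.1,
                          mpn_control = train_control(epochs = 500, lr = 0.02,
                                                      target_rel_rms = 0.20),
                          sn_control = train_control(epochs = 600, lr = 0.02,
                                                     target_rel_rms = 0.02),
                          window_planes = 2, window_retention = 1,
                          window_weight = 1, sn_relax = c(0.1, 0.7),
                          entropy_bins = 64) {
  list(near_distance = near_distance, subsample_fraction = subsample_fraction,
       weight_floor = weight_floor, mpn_control = mpn_control,
       sn_control = sn_control, window_planes = window_planes,
       window_retention = window_retention, window_weight = window_weight,
       sn_relax = rep(sn_relax, length.out = 2), entropy_bins = entropy_bins)
}

#' One AutoP cycle
#'
#' Runs the two FEAs for every active plane at one load step (2 executions
#' per plane), assembles the training fields, applies subsampling and
#' spatial weighting (multi-plane), trains the active network, and returns
#' a model usable by the next cycle. An FEA failure skips that plane's data
#' for the cycle with a warning; it is never silent.
#'
#' @param model a `cannccm`.
#' @param mesh an `autop_mesh`.
#' @param meas a `plane_measurements`.
#' @param planes integer indices of the active planes.
#' @param step_index load step.
#' @param phase `"mpn"` (first pass, S frozen at 1) or `"sn"` (MPN frozen).
#' @param opts [autop_options()].
#' @param extra_fields history-window fields mixed into SN training.
#' @param seed seed for the subsampling draw.
#' @param subsample_far apply far-field spatial subsampling. Default: on
#'   whenever a multi-plane model is being developed (the measurement set
#'   holds more than one plane); planar single-plane imaging keeps all
#'   points.
#' @param relax SN under-relaxation factor for this cycle; default the
#'   joint factor when several planes are active, else the individual one.
#' @return list with `model`, `fields` (one `training_field` per plane) and
#'   `log` (one row per FEA execution).
#' @export
autop_cycle <- function(model, mesh, meas, planes, step_index,
                        phase = c("sn", "mpn"), opts = autop_options(),
                        extra_fields = list(), seed = 1L,
                        subsample_far = length(meas$planes) > 1,
                        relax = NULL) {
  phase <- match.arg(phase)
  if (length(planes) == 0) stop("no active compression planes")
  fields <- list()
  log <- list()
  multi <- isTRUE(subsample_far)
  for (pi in planes) {
    pid <- meas$planes[[pi]]$plane_id
    pose <- meas$planes[[pi]]$pose
    res <- tryCatch({
      ss <- run_fea_sigma(mesh, model, meas, pi, step_index)
      se <- run_fea_epsilon(mesh, model, meas, pi, step_index)
      list(ss = ss, se = se)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("FEA failed for plane %s step %d: %s -- training data withheld",
                      pid, step_index, conditionMessage(res)), call. = FALSE)
      log[[length(log) + 1L]] <- data.frame(
        plane_id = pid, step = step_index, kind = "sigma+epsilon", ok = FALSE)
      next
    }
    log[[length(log) + 1L]] <- data.frame(
      plane_id = pid, step = step_index, kind = "sigma", ok = TRUE)
    log[[length(log) + 1L]] <- data.frame(
      plane_id = pid, step = step_index, kind = "epsilon", ok = TRUE)
    fld <- training_field(mesh, res$ss, res$se, pid, step_index)
    fld <- apply_focus(fld, pose, opts, do_subsample = multi,
                       seed = seed + 7L * pi + step_index)
    fields[[length(fields) + 1L]] <- fld
  }
  if (length(fields)) {
    train_set <- pool_fields(c(fields, extra_fields), masked = TRUE)
    if (phase == "mpn") {
      model <- train_mpn(model, train_set$eps, train_set$sigma,
                         weights = train_set$weight, control = opts$mpn_control)
    } else {
      a <- if (!is.null(relax)) relax else
        opts$sn_relax[if (length(planes) > 1) 2 else 1]
      target <- train_set$sigma
      if (a < 1) {
        sig_prev <- cannccm_stress(model, train_set$x, train_set$eps)
        target <- (1 - a) * sig_prev + a * target
      }
      model <- train_sn(model, train_set$x, train_set$eps, target,
                        weights = train_set$weight, control = opts$sn_control)
    }
  }
  list(model = model, fields = fields, log = do.call(rbind, log))
}

# concatenate training fields; masked = TRUE restricts to selected points
pool_fields <- function(fields, masked = FALSE) {
  take <- function(f, what) {
    m <- if (masked) f$mask else rep(TRUE, nrow(f$x))
    f[[what]][m, , drop = FALSE]
  }
  list(
    x = do.call(rbind, lapply(fields, take, "x")),
    sigma = do.call(rbind, lapply(fields, take, "sigma")),
    eps = do.call(rbind, lapply(fields, take, "eps")),
    eps_force = do.call(rbind, lapply(fields, take, "eps_force")),
    weight = unlist(lapply(fields, function(f)
      f$weight[if (masked) f$mask else TRUE])),
    key = unlist(lapply(fields, function(f) {
      m <- if (masked) which(f$mask) else seq_len(nrow(f$x))
      sprintf("%s/%d/%d", f$plane_id, f$step_index, m)
    })))
}

# thin a field for the history window: random retention, scaled weight
window_retain <- function(field, retention, weight_mult, seed) {
  keep <- field$mask
  idx <- which(keep)
  if (retention < 1 && length(idx)) {
    rng <- rng_stream(seed)
    n_keep <- max(1L, floor(retention * length(idx)))
    sel <- rng$sample(idx, n_keep)
    keep[] <- FALSE
    keep[sel] <- TRUE
  }
  field$mask <- keep
  field$weight <- field$weight * weight_mult
  field
}
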