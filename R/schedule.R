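#' Multi-plane training schedule
#'
#' The staged, time-efficient training schedule: the MPN is trained for one pass
#' on the first compression plane with all scale factors held at 1; then,
#' with the MPN frozen, the SN is trained on each plane individually
#' (two passes per plane by default) while a history window mixes in
#' training data from the most recently introduced planes; finally all
#' planes are trained simultaneously for the joint passes.
#'
#' @param mpn_passes passes of the MPN phase (default 1).
#' @param sn_passes_per_plane SN passes per individually introduced plane
#'   (default 2).
#' @param joint_passes simultaneous all-plane passes (default 4).
#' @param plane_order permutation of plane indices; default acquisition
#'   order.
#' @export
new_schedule <- function(mpn_passes = 1, sn_passes_per_plane = 2,
                         joint_passes = 4, plane_order = NULL) {
  stopifnot(mpn_passes >= 0, sn_passes_per_plane >= 0, joint_passes >= 0)
  structure(list(mpn_passes = as.integer(mpn_passes),
                 sn_passes_per_plane = as.integer(sn_passes_per_plane),
                 joint_passes = as.integer(joint_passes),
                 plane_order = plane_order),
            class = "autop_schedule")
}

#' One pass through the measurement data
#'
#' Cycles through all recorded load steps in acquisition order, executing
#' one [autop_cycle()] per load step.
#'
#' @inheritParams autop_cycle
#' @return list with `model`, `fields` (pooled over the pass's cycles) and
#'   `log`.
#' @export
run_pass <- function(model, mesh, meas, planes, phase = c("sn", "mpn"),
                     opts = autop_options(), extra_fields = list(), seed = 1L,
                     relax = NULL) {
  phase <- match.arg(phase)
  n_steps <- length(meas$planes[[planes[1]]]$steps)
  fields <- list()
  logs <- list()
  for (k in seq_len(n_steps)) {
    cyc <- autop_cycle(model, mesh, meas, planes, k, phase, opts,
                       extra_fields = extra_fields, seed = seed + 1000L * k,
                       relax = relax)
    model <- cyc$model
    fields <- c(fields, cyc$fields)
    logs[[k]] <- cyc$log
  }
  model$meta$passes <- model$meta$passes + 1L
  model$meta$phase <- phase
  list(model = model, fields = fields, log = do.call(rbind, logs))
}

pass_stats <- function(fields, extra_fields, prev, bins, opts) {
  sel <- pool_fields(c(fields, extra_fields), masked = TRUE)
  all_pts <- pool_fields(fields, masked = FALSE)
  if (is.null(bins)) bins <- make_bins(sel$sigma, opts$entropy_bins)
  H <- stress_entropy(sel$sigma, bins)
  eta <- strain_reversibility(sel$eps_force, sel$eps, opts$entropy_bins)
  delta <- if (is.null(prev)) NA_real_ else
    stress_convergence(all_pts$sigma, prev$sigma, all_pts$key, prev$key)
  list(H = H, eta = eta, delta = delta,
       mean_abs = mean(abs(all_pts$sigma)),
       prev = list(sigma = all_pts$sigma, key = all_pts$key),
       bins = bins)
}

#' Run the full AutoP training schedule
#'
#' Executes the three schedule phases on a measurement set, appending the
#' three test statistics (stress entropy, strain reversibility, stress
#' convergence) and the advisory decision after every pass. When a pass
#' introduces a new plane, the statistics are computed on the union of the
#' newly generated training data and the retained history-window data, so
#' they reflect what the new plane *adds* to the training environment.
#'
#' @param meas a `plane_measurements` with at least one plane.
#' @param mesh the `autop_mesh` the measurements refer to.
#' @param schedule a [new_schedule()].
#' @param opts [autop_options()].
#' @param model optionally a pre-initialized or pre-trained `cannccm`
#'   (default: fresh model seeded with `seed`).
#' @param seed integer; governs model initialization, subsampling draws and
#'   history-window retention. Two runs with the same seed and data are
#'   identical.
#' @return list with `model`, `history` (one tibble row per pass:
#'   `pass, phase, planes_active, H_sigma, eta_eps, delta_sigma_bar,
#'   mean_abs_sigma, advice`) and `log` (one row per FEA execution).
#' @export
run_schedule <- function(meas, mesh, schedule = new_schedule(),
                         opts = autop_options(), model = NULL, seed = 1L) {
  stopifnot(inherits(meas, "plane_measurements"))
  n_planes <- length(meas$planes)
  if (n_planes < 1) stop("at least one compression plane is required")
  if (any(abs(unlist(meas$mesh_spec$extent) - mesh$extent) > 1e-9) ||
      abs(meas$mesh_spec$element_size - mesh$h) > 1e-9)
    stop("measurements were recorded on a different mesh")
  order <- schedule$plane_order
  if (is.null(order)) order <- seq_len(n_planes)
  if (!setequal(order, seq_len(n_planes)))
    stop("plane_order must be a permutation of the available planes")
  if (is.null(model)) model <- new_cannccm(mesh, seed = seed)

  history <- list()
  logs <- list()
  window <- list()   # per recently introduced plane: its last fields
  prev <- NULL; bins <- NULL
  pass_no <- 0L

  record <- function(res, phase, planes, extra) {
    pass_no <<- pass_no + 1L
    st <- pass_stats(res$fields, extra, prev, bins, opts)
    prev <<- st$prev; bins <<- st$bins
    logs[[length(logs) + 1L]] <<- cbind(pass = pass_no, res$log)
    rec <- tibble::tibble(
      pass = pass_no, phase = phase,
      planes_active = paste(vapply(planes, function(i) meas$planes[[i]]$plane_id, ""),
                            collapse = "+"),
      H_sigma = st$H, eta_eps = st$eta, delta_sigma_bar = st$delta,
      mean_abs_sigma = st$mean_abs)
    core <- c("eta_eps", "delta_sigma_bar", "mean_abs_sigma")
    hist_df <- do.call(rbind, c(lapply(history, function(h) h[, core]),
                                list(rec[, core])))
    rec$advice <- advise(hist_df)
    history[[length(history) + 1L]] <<- rec
  }

  # phase 1: MPN on the first plane, scale factors held at 1
  for (p in seq_len(schedule$mpn_passes)) {
    res <- run_pass(model, mesh, meas, order[1], "mpn", opts,
                    seed = seed + 13L * pass_no)
    model <- res$model
    record(res, "mpn", order[1], list())
  }

  # phase 2: MPN frozen, SN per plane individually with history windowing
  for (pi in order) {
    extra <- list()
    if (length(window)) {
      recent <- utils::tail(window, opts$window_planes)
      for (wf in unlist(recent, recursive = FALSE))
        extra[[length(extra) + 1L]] <- window_retain(
          wf, opts$window_retention, opts$window_weight,
          seed + 31L * length(extra) + pass_no)
    }
    res <- NULL
    for (p in seq_len(schedule$sn_passes_per_plane)) {
      res <- run_pass(model, mesh, meas, pi, "sn", opts,
                      extra_fields = extra, seed = seed + 13L * pass_no)
      model <- res$model
      record(res, "sn", pi, extra)
    }
    if (!is.null(res)) window[[length(window) + 1L]] <- res$fields
  }

  # phase 3: all planes simultaneously (MPN stays frozen)
  for (p in seq_len(schedule$joint_passes)) {
    res <- run_pass(model, mesh, meas, order, "sn", opts,
                    seed = seed + 13L * pass_no)
    model <- res$model
    record(res, "joint", order, list())
  }

  list(model = model,
       history = do.call(rbind, history),
       log = tibble::as_tibble(do.call(rbind, logs)))
}

#' Plot a statistic history
#'
#' Stress entropy, strain reversibility and stress convergence versus pass.
#' @param object the `history` tibble from [run_schedule()].
#' @param ... unused.
#' @export
autoplot.autop_history <- function(object, ...) {
  df <- rbind(
    data.frame(pass = object$pass, stat = "H(sigma) [bits]", value = object$H_sigma),
    data.frame(pass = object$pass, stat = "eta_eps", value = object$eta_eps),
    data.frame(pass = object$pass, stat = "delta sigma-bar [kPa]",
               value = object$delta_sigma_bar))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pass, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~stat, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "training pass", y = NULL)
}

#' @rdname autoplot.autop_history
#' @param history a schedule history tibble.
#' @export
plot_history <- function(history) {
  class(history) <- c("autop_history", class(history))
  autoplot.autop_history(history)
}
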