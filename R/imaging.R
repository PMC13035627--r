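#' Specify an image plane
#'
#' Image planes are independent of the compression planes: any plane
#' through the volume may be rendered. The plane is parameterized by an
#' origin and two orthonormal in-plane direction vectors.
#'
#' @param origin 3-vector (mm), the pixel-grid corner.
#' @param u_vec,v_vec in-plane unit vectors (orthonormalized internally;
#'   an error is raised if they are parallel).
#' @param extents length-2 (mm): image size along `u_vec` and `v_vec`.
#' @param pixel_size pixel spacing (mm).
#' @export
image_plane_spec <- function(origin, u_vec, v_vec, extents, pixel_size = 0.5) {
  origin <- as.numeric(origin); u <- as.numeric(u_vec); v <- as.numeric(v_vec)
  stopifnot(length(origin) == 3, length(u) == 3, length(v) == 3,
            length(extents) == 2, all(extents > 0), pixel_size > 0)
  u <- u / sqrt(sum(u^2))
  v <- v - sum(v * u) * u
  nv <- sqrt(sum(v^2))
  if (nv < 1e-9) stop("in-plane vectors are parallel")
  v <- v / nv
  structure(list(origin = origin, u = u, v = v,
                 extents = as.numeric(extents), pixel_size = pixel_size),
            class = "image_plane_spec")
}

#' Render a Young's-modulus image in a plane
#'
#' Probes the CaNNCM directly at each pixel's 3-D location (the model is
#' continuous in position, so no nearest-integration-point lookup is
#' involved). Pixels outside the meshed volume are missing (`NA`), never
#' fabricated.
#'
#' @param model a trained or initialized `cannccm`.
#' @param mesh the `autop_mesh` defining the volume.
#' @param plane an [image_plane_spec()].
#' @return a `modulus_image`: matrix of E (kPa, rows = v axis, cols = u
#'   axis), the plane spec and provenance.
#' @export
render_modulus <- function(model, mesh, plane) {
  stopifnot(inherits(plane, "image_plane_spec"))
  su <- seq(plane$pixel_size / 2, plane$extents[1] - plane$pixel_size / 2,
            by = plane$pixel_size)
  sv <- seq(plane$pixel_size / 2, plane$extents[2] - plane$pixel_size / 2,
            by = plane$pixel_size)
  if (!length(su) || !length(sv)) stop("image extents smaller than one pixel")
  pts <- matrix(0, length(su) * length(sv), 3)
  k <- 1L
  for (j in seq_along(sv)) for (i in seq_along(su)) {
    pts[k, ] <- plane$origin + su[i] * plane$u + sv[j] * plane$v
    k <- k + 1L
  }
  inside <- pts[, 1] >= -1e-9 & pts[, 1] <= mesh$extent[1] + 1e-9 &
    pts[, 2] >= -1e-9 & pts[, 2] <= mesh$extent[2] + 1e-9 &
    pts[, 3] >= -1e-9 & pts[, 3] <= mesh$extent[3] + 1e-9
  if (!any(inside)) stop("image plane does not intersect the meshed volume")
  E <- rep(NA_real_, nrow(pts))
  E[inside] <- probe_youngs_modulus(model, pts[inside, , drop = FALSE])
  img <- matrix(E, length(sv), length(su), byrow = TRUE)
  structure(list(E = img, u_mm = su, v_mm = sv, plane = plane,
                 provenance = list(passes = model$meta$passes,
                                   phase = model$meta$phase)),
            class = "modulus_image")
}

#' @export
print.modulus_image <- function(x, ...) {
  cat(sprintf("<modulus_image> %d x %d px (%.2g mm/px); E range %.3g..%.3g kPa (%d missing)\n",
              nrow(x$E), ncol(x$E), x$plane$pixel_size,
              min(x$E, na.rm = TRUE), max(x$E, na.rm = TRUE), sum(is.na(x$E))))
  invisible(x)
}

#' Tidy a modulus image
#' @param x a `modulus_image`.
#' @param ... unused.
#' @export
tidy.modulus_image <- function(x, ...) {
  tibble::tibble(
    u = rep(x$u_mm, each = length(x$v_mm)),
    v = rep(x$v_mm, times = length(x$u_mm)),
    E = as.vector(x$E))
}

#' @export
autoplot.modulus_image <- function(object, ...) {
  df <- tidy.modulus_image(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$u, y = .data$v, fill = .data$E)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "E (kPa)", na.value = "grey50") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "in-plane u (mm)", y = "in-plane v (mm)")
}

#' Export a modulus image
#'
#' `write_modulus_png()` writes a 16-bit grayscale PNG plus a JSON sidecar
#' with the kPa calibration (`E = offset + slope * code`) and the missing
#' pixel sentinel (code 0). `write_modulus_csv()` writes the pixel grid
#' with `NA` for missing pixels.
#'
#' @param img a `modulus_image`.
#' @param path output path (`.png` / `.csv`).
#' @export
write_modulus_png <- function(img, path) {
  E <- img$E
  fin <- is.finite(E)
  if (!any(fin)) stop("image has no finite pixels")
  lo <- min(E[fin]); hi <- max(E[fin])
  slope <- if (hi > lo) (hi - lo) / 65534 else 1
  code <- matrix(0L, nrow(E), ncol(E))
  code[fin] <- 1L + as.integer(round((E[fin] - lo) / slope))
  png::writePNG(code[rev(seq_len(nrow(code))), , drop = FALSE] / 65535, path)
  side <- sub("\\.png$", ".json", path)
  jsonlite::write_json(list(units = "kPa", offset = lo - slope, slope = slope,
                            missing_code = 0, pixel_mm = img$plane$pixel_size),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_modulus_png
#' @export
write_modulus_csv <- function(img, path) {
  utils::write.csv(img$E, path, row.names = FALSE)
  invisible(path)
}

#' What-if re-simulation with a trained model
#'
#' Once a CaNNCM is trained, numerical experiments can be performed on the
#' meshed volume: any force- or displacement-driven boundary-condition set
#' is solved against the learned material to predict the stress and strain
#' patterns under loading conditions that were never measured (for
#' instance, an enlarged compressor covering half the top surface).
#'
#' @param model a `cannccm`.
#' @param mesh an `autop_mesh`.
#' @param bcs an `autop_bcs`.
#' @return an `autop_solution`.
#' @export
what_if <- function(model, mesh, bcs) {
  fem_solve(mesh, cannccm_material(model, mesh), bcs)
}
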