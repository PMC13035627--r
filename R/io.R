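# Structured, versioned JSON containers. Numeric arrays are stored as
# base64-encoded little-endian doubles so checkpoints round-trip
# bit-identically.

enc_num <- function(x) {
  list(dim = if (is.matrix(x)) dim(x) else length(x),
       b64 = jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8L,
                                           endian = "little")))
}

dec_num <- function(e) {
  v <- readBin(jsonlite::base64_dec(e$b64), "double", n = prod(unlist(e$dim)),
               size = 8L, endian = "little")
  if (length(e$dim) == 2) matrix(v, unlist(e$dim)[1], unlist(e$dim)[2]) else v
}

#' Save / load a CaNNCM checkpoint
#'
#' Single-file JSON container holding both networks, normalization constants
#' and schedule state; weight arrays round-trip bit-identically.
#'
#' @param model a `cannccm`.
#' @param path file path (`.json`).
#' @export
cannccm_save <- function(model, path) {
  stopifnot(inherits(model, "cannccm"))
  num_keys_mpn <- c("W1", "b1", "W2", "b2", "W3", "A", "A0",
                    "eps_scale", "sig_scale")
  num_keys_sn <- c("V1", "c1", "V2", "c2", "v3", "c3", "center", "halfw")
  obj <- list(
    format = "autoprog-cannccm", version = 1L,
    extent = model$extent,
    mpn = c(lapply(model$mpn[num_keys_mpn], enc_num),
            model$mpn["scales_fixed"]),
    sn = lapply(model$sn[num_keys_sn], enc_num),
    meta = model$meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname cannccm_save
#' @export
cannccm_load <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "autoprog-cannccm"))
    stop("not a CaNNCM checkpoint: ", path)
  mpn <- lapply(obj$mpn[c("W1", "b1", "W2", "b2", "W3", "A", "A0",
                          "eps_scale", "sig_scale")], dec_num)
  mpn$scales_fixed <- isTRUE(obj$mpn$scales_fixed)
  sn <- lapply(obj$sn, dec_num)
  sn$v3 <- matrix(sn$v3, nrow = 1)
  sn$c3 <- as.numeric(sn$c3)
  meta <- obj$meta
  meta$passes <- as.integer(meta$passes)
  structure(list(mpn = mpn, sn = sn, extent = as.numeric(unlist(obj$extent)),
                 meta = meta),
            class = "cannccm")
}

#' Save / load a measurement set
#'
#' Versioned JSON layout: `planes/<k>/{pose, footprint, steps/{u, f,
#' node_ids, uy}}` plus the mesh description the measurements refer to.
#'
#' @param meas a `plane_measurements` object (see [simulate_plane()]).
#' @param path file path (`.json`).
#' @export
measurements_save <- function(meas, path) {
  stopifnot(inherits(meas, "plane_measurements"))
  obj <- list(
    format = "autoprog-measurements", version = 1L,
    mesh = meas$mesh_spec,
    planes = lapply(meas$planes, function(p) list(
      plane_id = p$plane_id,
      pose = p$pose,
      footprint_nodes = p$footprint_nodes,
      measured_nodes = p$measured_nodes,
      steps = lapply(p$steps, function(s) c(
        list(u = s$u, f = s$f, uy = enc_num(s$uy)),
        if (!is.null(s$u3)) list(u3 = enc_num(s$u3)))))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname measurements_save
#' @export
measurements_load <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "autoprog-measurements"))
    stop("not a measurement container: ", path)
  planes <- lapply(obj$planes, function(p) list(
    plane_id = as.character(p$plane_id),
    pose = lapply(p$pose, function(v)
      if (is.list(v)) lapply(v, function(e) unlist(e)) else v),
    footprint_nodes = as.integer(unlist(p$footprint_nodes)),
    measured_nodes = as.integer(unlist(p$measured_nodes)),
    steps = lapply(p$steps, function(s) c(
      list(u = as.numeric(s$u), f = as.numeric(s$f), uy = dec_num(s$uy)),
      if (!is.null(s$u3)) list(u3 = dec_num(s$u3))))))
  structure(list(
    mesh_spec = lapply(obj$mesh, function(v) if (is.list(v)) unlist(v) else v),
    planes = planes), class = "plane_measurements")
}

#' Export a mesh with fields to legacy-ASCII VTK
#'
#' Writes an unstructured-grid VTK file with the hexahedral cells plus
#' optional point data (nodal displacements) and cell data (stress/strain
#' averaged over each element's integration points) for visualization.
#'
#' @param mesh an `autop_mesh`.
#' @param path output file (`.vtk`).
#' @param solution optional `autop_solution` whose fields to attach.
#' @export
write_vtk <- function(mesh, path, solution = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  wl("# vtk DataFile Version 3.0")
  wl("autoprog field export (mm, kPa)")
  wl("ASCII")
  wl("DATASET UNSTRUCTURED_GRID")
  wl("POINTS %d double", mesh$n_nodes)
  writeLines(apply(mesh$nodes, 1, function(p) paste(format(p, digits = 10), collapse = " ")), con)
  wl("CELLS %d %d", mesh$n_elems, mesh$n_elems * 9L)
  writeLines(apply(mesh$elems - 1L, 1, function(e) paste(c(8L, e), collapse = " ")), con)
  wl("CELL_TYPES %d", mesh$n_elems)
  writeLines(rep("12", mesh$n_elems), con)
  if (!is.null(solution)) {
    wl("POINT_DATA %d", mesh$n_nodes)
    wl("VECTORS displacement double")
    writeLines(apply(solution$u, 1, function(p) paste(format(p, digits = 10), collapse = " ")), con)
    wl("CELL_DATA %d", mesh$n_elems)
    avg6 <- function(M) {
      out <- matrix(0, mesh$n_elems, 6)
      for (q in 1:8) out <- out + M[(seq_len(mesh$n_elems) - 1L) * 8L + q, , drop = FALSE]
      out / 8
    }
    for (fld in c("stress", "strain")) {
      M <- avg6(solution[[fld]])
      for (k in 1:6) {
        wl("SCALARS %s_%s double 1", fld, voigt_labels()[k])
        wl("LOOKUP_TABLE default")
        writeLines(format(M[, k], digits = 10), con)
      }
    }
  }
  invisible(path)
}

#' Export integration-point fields as CSV
#'
#' Columns `x,y,z,sig_xx..sig_yz,eps_xx..eps_yz` (mm / kPa), one row per
#' integration point.
#' @inheritParams write_vtk
#' @param solution an `autop_solution`.
#' @export
write_field_csv <- function(mesh, solution, path) {
  df <- data.frame(mesh$ip_coords, solution$stress, solution$strain)
  names(df) <- c("x", "y", "z", paste0("sig_", voigt_labels()),
                 paste0("eps_", voigt_labels()))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
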