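#' Build a regular hexahedral mesh
#'
#' Discretizes a rectangular volume into 8-node hexahedral elements (C3D8)
#' with full 2x2x2 Gauss integration. The compression axis is y: the probe
#' contacts the `y = extent[2]` face and the phantom rests on the rigid
#' no-slip `y = 0` face. The origin sits at the volume's bottom corner.
#'
#' All geometry is in millimetres. Voigt order throughout the package is
#' (xx, yy, zz, xy, xz, yz) with engineering shear strains.
#'
#' @param extent length-3 numeric, edge lengths of the volume (mm). Each
#'   component must be a positive integer multiple of `element_size`.
#' @param element_size element edge length (mm).
#' @return An object of class `autop_mesh` with node coordinates, element
#'   connectivity, per-element dof indices, integration-point positions and
#'   precomputed strain-displacement matrices.
#' @examples
#' m <- build_hex_mesh(c(8, 8, 8), 4)
#' m$n_elems  # 8
#' @export
build_hex_mesh <- function(extent, element_size) {
  extent <- as.numeric(extent)
  h <- as.numeric(element_size)
  if (length(extent) != 3 || any(!is.finite(extent)) || any(extent <= 0))
    stop("`extent` must be three positive lengths (mm)")
  if (length(h) != 1 || !is.finite(h) || h <= 0)
    stop("`element_size` must be a positive length (mm)")
  ncell <- extent / h
  if (any(abs(ncell - round(ncell)) > 1e-9))
    stop(sprintf(
      "extent (%s) mm is not divisible by element_size (%g) mm; choose an extent that is an integer multiple of the element size",
      paste(extent, collapse = ", "), h))
  ncell <- as.integer(round(ncell))
  nn <- ncell + 1L

  xs <- seq(0, extent[1], by = h)
  ys <- seq(0, extent[2], by = h)
  zs <- seq(0, extent[3], by = h)
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs, KEEP.OUT.ATTRS = FALSE))
  dimnames(nodes) <- NULL

  nid <- function(ix, iy, iz) ix + (iy - 1L) * nn[1] + (iz - 1L) * nn[1] * nn[2]

  # local node order: (-,-,-) (+,-,-) (+,+,-) (-,+,-) then same with z+
  grid <- expand.grid(ix = seq_len(ncell[1]), iy = seq_len(ncell[2]),
                      iz = seq_len(ncell[3]), KEEP.OUT.ATTRS = FALSE)
  ix <- grid$ix; iy <- grid$iy; iz <- grid$iz
  elems <- cbind(
    nid(ix,      iy,      iz),
    nid(ix + 1L, iy,      iz),
    nid(ix + 1L, iy + 1L, iz),
    nid(ix,      iy + 1L, iz),
    nid(ix,      iy,      iz + 1L),
    nid(ix + 1L, iy,      iz + 1L),
    nid(ix + 1L, iy + 1L, iz + 1L),
    nid(ix,      iy + 1L, iz + 1L)
  )
  storage.mode(elems) <- "integer"
  ne <- nrow(elems)

  # signs of the local corners in (xi, eta, zeta)
  sgn <- rbind(
    c(-1, -1, -1), c(1, -1, -1), c(1, 1, -1), c(-1, 1, -1),
    c(-1, -1,  1), c(1, -1,  1), c(1, 1,  1), c(-1, 1,  1))
  g <- 1 / sqrt(3)
  gp <- as.matrix(expand.grid(xi = c(-g, g), eta = c(-g, g), zeta = c(-g, g)))
  dimnames(gp) <- NULL
  # regular grid: jacobian is diag(h/2), constant
  detJ <- (h / 2)^3
  wdetJ <- detJ  # gauss weights are all 1 for 2x2x2

  Bs <- vector("list", 8L)
  Ns <- matrix(0, 8, 8)  # shape values, row = gp, col = node
  for (q in 1:8) {
    xi <- gp[q, ]
    dNdx <- matrix(0, 8, 3)
    for (a in 1:8) {
      s <- sgn[a, ]
      Ns[q, a] <- prod(1 + xi * s) / 8
      # dN/dxi then chain through J^-1 = diag(2/h)
      dNdxi <- c(
        s[1] * (1 + xi[2] * s[2]) * (1 + xi[3] * s[3]),
        (1 + xi[1] * s[1]) * s[2] * (1 + xi[3] * s[3]),
        (1 + xi[1] * s[1]) * (1 + xi[2] * s[2]) * s[3]) / 8
      dNdx[a, ] <- dNdxi * (2 / h)
    }
    B <- matrix(0, 6, 24)
    for (a in 1:8) {
      cx <- 3L * (a - 1L) + 1L
      dx <- dNdx[a, 1]; dy <- dNdx[a, 2]; dz <- dNdx[a, 3]
      B[1, cx]     <- dx
      B[2, cx + 1] <- dy
      B[3, cx + 2] <- dz
      B[4, cx]     <- dy; B[4, cx + 1] <- dx
      B[5, cx]     <- dz; B[5, cx + 2] <- dx
      B[6, cx + 1] <- dz; B[6, cx + 2] <- dy
    }
    Bs[[q]] <- B
  }

  # integration-point global coordinates, row ordering (e - 1) * 8 + q
  centers <- (nodes[elems[, 1], , drop = FALSE] + nodes[elems[, 7], , drop = FALSE]) / 2
  ip_coords <- matrix(0, ne * 8L, 3)
  for (q in 1:8) ip_coords[(seq_len(ne) - 1L) * 8L + q, ] <-
    centers + matrix(gp[q, ] * h / 2, ne, 3, byrow = TRUE)

  dof <- matrix(0L, ne, 24)
  for (a in 1:8) dof[, (3L * (a - 1L) + 1L):(3L * a)] <-
    cbind(3L * (elems[, a] - 1L) + 1L, 3L * (elems[, a] - 1L) + 2L, 3L * (elems[, a] - 1L) + 3L)

  structure(list(
    extent = extent, h = h, ncell = ncell,
    nodes = nodes, elems = elems, dof = dof,
    n_nodes = nrow(nodes), n_elems = ne, n_ip = ne * 8L,
    B = Bs, N = Ns, wdetJ = wdetJ, gp_local = gp,
    ip_coords = ip_coords
  ), class = "autop_mesh")
}

#' @export
print.autop_mesh <- function(x, ...) {
  cat(sprintf("<autop_mesh> %g x %g x %g mm, h = %g mm: %d elements, %d nodes, %d integration points\n",
              x$extent[1], x$extent[2], x$extent[3], x$h,
              x$n_elems, x$n_nodes, x$n_ip))
  invisible(x)
}

#' Nodes on a face of the meshed volume
#'
#' @param mesh an `autop_mesh`.
#' @param face one of `"xmin","xmax","ymin","ymax","zmin","zmax"`; y is the
#'   compression axis, so `"ymax"` is the probe contact face and `"ymin"` the
#'   supported bottom.
#' @return integer node indices.
#' @export
mesh_face_nodes <- function(mesh, face = c("ymin", "ymax", "xmin", "xmax", "zmin", "zmax")) {
  face <- match.arg(face)
  axis <- match(substr(face, 1, 1), c("x", "y", "z"))
  val <- if (substr(face, 2, 4) == "min") 0 else mesh$extent[axis]
  which(abs(mesh$nodes[, axis] - val) < 1e-9)
}

#' Nodes within a probe footprint on the top surface
#'
#' The probe footprint is a rectangle on the `y = extent[2]` face, centred at
#' `center_x`/`center_z`, spanning `length_mm` along x (the lateral array
#' direction) and `width_mm` along z (elevational). A footprint larger than
#' the phantom is clipped to the surface.
#'
#' @param mesh an `autop_mesh`.
#' @param center_z,center_x footprint centre (mm); `center_x` defaults to the
#'   middle of the face.
#' @param length_mm,width_mm footprint extents (mm); defaults are the 11 x 46
#'   mm contact area of an 8-MHz linear array.
#' @return integer node indices on the top face under the probe.
#' @export
footprint_nodes <- function(mesh, center_z, center_x = mesh$extent[1] / 2,
                            length_mm = 46, width_mm = 11) {
  top <- mesh_face_nodes(mesh, "ymax")
  xy <- mesh$nodes[top, , drop = FALSE]
  keep <- abs(xy[, 1] - center_x) <= length_mm / 2 + 1e-9 &
    abs(xy[, 3] - center_z) <= width_mm / 2 + 1e-9
  sel <- top[keep]
  if (length(sel) == 0) stop("probe footprint does not intersect the top surface")
  sel
}

#' Nodes in the measurement slab of a compression plane
#'
#' The ultrasound scan plane is an x-y plane at `center_z`; axial
#' displacements are tracked at all mesh nodes within half an element of it,
#' across the lateral footprint and (by default) the full depth.
#'
#' @inheritParams footprint_nodes
#' @param half_thickness slab half-thickness (mm); default half an element.
#' @return integer node indices.
#' @export
slab_nodes <- function(mesh, center_z, center_x = mesh$extent[1] / 2,
                       length_mm = 46, half_thickness = mesh$h / 2) {
  keep <- abs(mesh$nodes[, 3] - center_z) <= half_thickness + 1e-9 &
    abs(mesh$nodes[, 1] - center_x) <= length_mm / 2 + 1e-9
  which(keep)
}
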