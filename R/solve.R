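#' Boundary-condition sets
#'
#' Collects the constraints and loads for one finite-element solve. Each
#' degree of freedom may appear at most once across prescribed displacements,
#' nodal loads and a rigid footprint load.
#'
#' Force-driven solves apply the measured total force through a rigid
#' footprint: the axial (y) dofs of all footprint nodes are tied to a single
#' master dof that carries the total force, modelling the flat rigid probe
#' the force sensor sits behind. A `"pressure"`-style alternative
#' (tributary-area nodal loads) is available via `rigid = FALSE`.
#'
#' @param fixed data.frame with columns `node`, `axis` (1 = x, 2 = y, 3 = z)
#'   and `value` (prescribed displacement, mm).
#' @param loads data.frame with columns `node`, `axis`, `value` (force, N).
#' @param footprint integer node indices under the probe contact area (used
#'   for reaction accounting and rigid force application).
#' @param footprint_force total signed axial force (N) applied through the
#'   footprint (negative = compression). `NULL` when displacement-driven.
#' @param rigid logical; tie footprint axial dofs together when applying
#'   `footprint_force` (default) or distribute it as nodal loads.
#' @return an object of class `autop_bcs`.
#' @export
bc_set <- function(fixed = NULL, loads = NULL, footprint = integer(0),
                   footprint_force = NULL, rigid = TRUE) {
  empty <- data.frame(node = integer(0), axis = integer(0), value = numeric(0))
  fixed <- if (is.null(fixed)) empty else as.data.frame(fixed)
  loads <- if (is.null(loads)) empty else as.data.frame(loads)
  for (df in list(fixed, loads)) {
    if (!all(c("node", "axis", "value") %in% names(df)))
      stop("`fixed`/`loads` need columns node, axis, value")
    if (any(!df$axis %in% 1:3)) stop("axis must be 1 (x), 2 (y) or 3 (z)")
  }
  fdof <- 3L * (fixed$node - 1L) + fixed$axis
  ldof <- 3L * (loads$node - 1L) + loads$axis
  rdof <- if (!is.null(footprint_force) && isTRUE(rigid))
    3L * (as.integer(footprint) - 1L) + 2L else integer(0)
  all_dofs <- c(fdof, ldof, rdof)
  if (anyDuplicated(all_dofs))
    stop("a degree of freedom appears more than once across fixed dofs, loads and the rigid footprint")
  structure(list(fixed = fixed, loads = loads,
                 footprint = as.integer(footprint),
                 footprint_force = footprint_force, rigid = isTRUE(rigid)),
            class = "autop_bcs")
}

# Assemble the global stiffness (N/m given mm/kPa element quantities, which
# coincide numerically with SI) as a sparse symmetric matrix.
assemble_stiffness <- function(mesh, material) {
  nd <- 3L * mesh$n_nodes
  ne <- mesh$n_elems
  if (material$kind == "scaled") {
    Kg0 <- matrix(0, 8, 576)
    for (q in 1:8) {
      Kq <- crossprod(mesh$B[[q]], material$D0 %*% mesh$B[[q]]) * mesh$wdetJ
      Kg0[q, ] <- as.vector(Kq)
    }
    S <- t(matrix(material$scale, 8L, ne))      # ne x 8, row e = scales of its gps
    V <- S %*% Kg0                              # ne x 576
  } else {
    V <- matrix(0, ne, 576)
    for (e in seq_len(ne)) {
      Ke <- matrix(0, 24, 24)
      for (q in 1:8) {
        Dp <- material$D[, , (e - 1L) * 8L + q]
        Ke <- Ke + crossprod(mesh$B[[q]], Dp %*% mesh$B[[q]]) * mesh$wdetJ
      }
      V[e, ] <- as.vector(Ke)
    }
  }
  cols <- rep(1:24, each = 24)
  rows <- rep(1:24, times = 24)
  II <- mesh$dof[, rows, drop = FALSE]
  JJ <- mesh$dof[, cols, drop = FALSE]
  K <- Matrix::sparseMatrix(i = as.vector(II), j = as.vector(JJ),
                            x = as.vector(V), dims = c(nd, nd))
  Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
}

#' Solve a small-strain equilibrium problem
#'
#' Assembles the global stiffness from the per-integration-point material,
#' applies the boundary-condition set and solves the linear system by sparse
#' Cholesky factorization. Strains are recovered from the displacement
#' gradient at the 2x2x2 Gauss points and stresses from the material acting
#' on those strains.
#'
#' @param mesh an `autop_mesh`.
#' @param material an `autop_material` (see [material_uniform()]); stiffness
#'   in kPa.
#' @param bcs an `autop_bcs`.
#' @param tol relative-residual tolerance on the free equations.
#' @return an `autop_solution`: nodal displacements (mm, n_nodes x 3), Voigt
#'   strain and stress (n_ip x 6; kPa), the signed axial reaction on the
#'   footprint (N) and the achieved relative residual.
#' @export
fem_solve <- function(mesh, material, bcs, tol = 1e-10) {
  material <- material_check(material, mesh$n_ip)
  if (!inherits(bcs, "autop_bcs")) stop("`bcs` must come from bc_set()")
  nd <- 3L * mesh$n_nodes
  K <- assemble_stiffness(mesh, material)

  f_ext <- numeric(nd)
  if (nrow(bcs$loads))
    f_ext[3L * (bcs$loads$node - 1L) + bcs$loads$axis] <-
      f_ext[3L * (bcs$loads$node - 1L) + bcs$loads$axis] + bcs$loads$value

  fp_ydofs <- 3L * (bcs$footprint - 1L) + 2L
  red <- seq_len(nd)          # map full dof -> reduced dof (rigid tie)
  tied <- FALSE
  if (!is.null(bcs$footprint_force)) {
    if (length(bcs$footprint) == 0) stop("footprint_force given but no footprint nodes")
    if (bcs$rigid && length(fp_ydofs) > 1) {
      master <- fp_ydofs[1]
      red[fp_ydofs] <- master
      tied <- TRUE
      f_ext[master] <- f_ext[master] + bcs$footprint_force
    } else {
      # tributary-area distribution of a uniform pressure over the footprint
      w <- footprint_tributary(mesh, bcs$footprint)
      f_ext[fp_ydofs] <- f_ext[fp_ydofs] + bcs$footprint_force * w
    }
  }
  keep <- sort(unique(red))
  ridx <- match(red, keep)    # full dof -> index into reduced system
  if (tied) {
    Tm <- Matrix::sparseMatrix(i = seq_len(nd), j = ridx, x = 1,
                               dims = c(nd, length(keep)))
    Kr <- Matrix::forceSymmetric(Matrix::crossprod(Tm, K %*% Tm))
    fr <- as.numeric(Matrix::crossprod(Tm, f_ext))
  } else {
    Kr <- K; fr <- f_ext
  }

  fdof_full <- 3L * (bcs$fixed$node - 1L) + bcs$fixed$axis
  if (tied && any(fdof_full %in% fp_ydofs[-1]))
    stop("cannot prescribe a displacement on a dof tied to the rigid footprint")
  fdof <- ridx[fdof_full]
  uc <- bcs$fixed$value / 1000          # mm -> m
  nr <- nrow(Kr)
  if (length(fdof) == 0) stop("no prescribed displacements: rigid-body modes are unconstrained")
  free <- setdiff(seq_len(nr), fdof)

  rhs <- fr[free] - as.numeric(Kr[free, fdof, drop = FALSE] %*% uc)
  Kff <- Kr[free, free, drop = FALSE]
  uf <- tryCatch(
    as.numeric(Matrix::solve(Kff, rhs)),
    error = function(e) stop(
      "stiffness system is rank-deficient (insufficient constraints or non-SPD material): ",
      conditionMessage(e), call. = FALSE))
  res <- sqrt(sum((as.numeric(Kff %*% uf) - rhs)^2))
  den <- sqrt(sum(rhs^2))
  rel_res <- if (den > 0) res / den else res
  if (!is.finite(rel_res) || (den > 0 && rel_res > max(tol, 1e-8) * 100))
    stop(sprintf("solver residual %g exceeds tolerance", rel_res))

  ur <- numeric(nr)
  ur[free] <- uf
  ur[fdof] <- uc
  u_full <- ur[ridx] * 1000             # m -> mm, expand ties

  U <- matrix(u_full, ncol = 3, byrow = TRUE)   # n_nodes x 3 (mm)
  # strains/stresses at integration points
  ne <- mesh$n_elems
  Ue <- matrix(u_full[t(mesh$dof)], nrow = 24)  # 24 x ne
  eps <- matrix(0, mesh$n_ip, 6)
  for (q in 1:8) eps[(seq_len(ne) - 1L) * 8L + q, ] <- t(mesh$B[[q]] %*% Ue)
  sig <- material_stress(material, eps)

  # internal axial force carried by the footprint (N); in force-driven solves
  # this reproduces the applied total force to solver accuracy
  Ku <- as.numeric(K %*% (u_full / 1000))
  reaction <- if (length(fp_ydofs)) sum(Ku[fp_ydofs]) else NA_real_

  structure(list(u = U, strain = eps, stress = sig,
                 reaction_force = reaction, residual = rel_res,
                 footprint = bcs$footprint),
            class = "autop_solution")
}

# tributary-area weights for a uniform pressure over footprint nodes of a
# regular grid (interior 1, edges 1/2, corners 1/4, normalized to sum 1)
footprint_tributary <- function(mesh, fp) {
  xz <- mesh$nodes[fp, c(1, 3), drop = FALSE]
  w <- rep(1, length(fp))
  for (k in 1:2) {
    r <- range(xz[, k])
    if (diff(r) > 0) w[xz[, k] %in% r] <- w[xz[, k] %in% r] / 2
  }
  w / sum(w)
}

#' @export
print.autop_solution <- function(x, ...) {
  cat(sprintf("<autop_solution> %d nodes, %d integration points; |u|max = %.4g mm, footprint reaction = %.4g N\n",
              nrow(x$u), nrow(x$strain), max(abs(x$u)), x$reaction_force))
  invisible(x)
}

#' Tidy a field solution
#'
#' One row per integration point with position, Voigt strain and stress.
#' @param x an `autop_solution`.
#' @param mesh the mesh it was computed on.
#' @param ... unused.
#' @export
tidy.autop_solution <- function(x, mesh, ...) {
  tibble::as_tibble(data.frame(
    ip = seq_len(nrow(x$strain)),
    x = mesh$ip_coords[, 1], y = mesh$ip_coords[, 2], z = mesh$ip_coords[, 3],
    setNames(as.data.frame(x$strain), paste0("eps_", voigt_labels())),
    setNames(as.data.frame(x$stress), paste0("sig_", voigt_labels()))))
}

voigt_labels <- function() c("xx", "yy", "zz", "xy", "xz", "yz")
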