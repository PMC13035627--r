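#' Isotropic linear-elastic stiffness in Voigt form
#'
#' Returns the 6x6 stiffness relating Voigt strain (engineering shear) to
#' Voigt stress, order (xx, yy, zz, xy, xz, yz). Units follow `E`: pass kPa
#' to get kPa stresses.
#'
#' @param E Young's modulus.
#' @param nu Poisson's ratio, in (0, 0.5).
#' @export
iso_stiffness <- function(E, nu) {
  if (nu <= 0 || nu >= 0.5) stop("`nu` must lie in (0, 0.5)")
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- diag(c(rep(2 * mu, 3), rep(mu, 3)))
  D[1:3, 1:3] <- D[1:3, 1:3] + lam
  D
}

#' Material stiffness providers for the solver
#'
#' The solver consumes a *material*: the per-integration-point 6x6 stiffness.
#' Two forms are supported. The common, fast form is "scaled": one base
#' matrix `D0` (kPa) and a positive per-point scalar multiplier, covering
#' isotropic fields with a shared Poisson's ratio as well as the neural
#' constitutive model's tangent (base tangent times the spatial scale
#' factor). The general form is a full `6 x 6 x n_ip` array.
#'
#' @param E Young's modulus (kPa), scalar or one value per integration point.
#' @param nu Poisson's ratio.
#' @return a material object of class `autop_material`.
#' @export
material_uniform <- function(E, nu = 0.45) {
  stopifnot(length(E) == 1, E > 0)
  material_scaled(iso_stiffness(1, nu), E)
}

#' @param D0 base 6x6 stiffness (kPa).
#' @param scale positive scalar per integration point (recycled if length 1).
#' @rdname material_uniform
#' @export
material_scaled <- function(D0, scale) {
  D0 <- (D0 + t(D0)) / 2
  ev <- eigen(D0, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("material base stiffness is not positive definite")
  if (any(!is.finite(scale)) || any(scale <= 0))
    stop("material scale factors must be positive and finite")
  structure(list(kind = "scaled", D0 = D0, scale = scale), class = "autop_material")
}

#' @param D array `6 x 6 x n_ip` of per-point stiffness matrices (kPa).
#' @rdname material_uniform
#' @export
material_pointwise <- function(D) {
  stopifnot(length(dim(D)) == 3, dim(D)[1] == 6, dim(D)[2] == 6)
  structure(list(kind = "pointwise", D = D), class = "autop_material")
}

# expand a material to per-ip scale vector / validate against a mesh
material_check <- function(material, n_ip) {
  if (!inherits(material, "autop_material")) stop("not an `autop_material`")
  if (material$kind == "scaled") {
    s <- material$scale
    if (length(s) == 1) s <- rep(s, n_ip)
    if (length(s) != n_ip)
      stop(sprintf("material has %d scale factors but the mesh has %d integration points",
                   length(material$scale), n_ip))
    material$scale <- s
  } else {
    if (dim(material$D)[3] != n_ip)
      stop("pointwise material does not match the mesh integration points")
    for (p in seq_len(n_ip)) {
      Dp <- material$D[, , p]
      if (max(abs(Dp - t(Dp))) > 1e-8 * max(abs(Dp)) ||
          min(eigen((Dp + t(Dp)) / 2, symmetric = TRUE, only.values = TRUE)$values) <= 0)
        stop(sprintf("material stiffness at integration point %d is not symmetric positive definite", p))
    }
  }
  material
}

# stress (kPa) from strain rows (n x 6) under a checked material
material_stress <- function(material, eps) {
  if (material$kind == "scaled") {
    (eps %*% t(material$D0)) * material$scale
  } else {
    out <- matrix(0, nrow(eps), 6)
    for (p in seq_len(nrow(eps))) out[p, ] <- material$D[, , p] %*% eps[p, ]
    out
  }
}
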