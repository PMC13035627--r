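#' Cartesian neural network constitutive models
#'
#' A CaNNCM pairs two shallow feed-forward networks: the material property
#' network (MPN) maps scaled Voigt strain to Voigt stress and encodes the
#' spatially averaged constitutive response, while the spatial network (SN)
#' maps position to a strictly positive scalar strain scale factor S(x) that
#' adjusts the slope of the average stress-strain response locally. Stress
#' evaluation is by construction `mpn(S(x) * eps)`.
#'
#' The MPN output is anchored so that zero strain maps exactly to zero
#' stress (`sigma(eps) = net(eps) - net(0)`), and a trainable 6x6 linear
#' term is carried alongside the tanh hidden layers so that linear-elastic
#' responses are representable exactly. A freshly initialized SN outputs
#' exactly 1 everywhere (its final layer starts at zero), so a fresh model
#' is spatially homogeneous.
#'
#' @param bounds either an `autop_mesh` or a length-3 extent (mm); positions
#'   are normalized to this box for the SN input.
#' @param mpn_hidden,sn_hidden hidden-layer widths.
#' @param eps_scale,sig_scale input/output normalization constants (strain
#'   units / kPa). `NA` (default) means "provisional": they are re-derived
#'   from the first training data (95th percentile of absolute values) in a
#'   function-preserving way.
#' @param init_E,init_nu the homogeneous isotropic starting guess encoded in
#'   the fresh MPN's linear term, so a fresh model is immediately usable as
#'   an FEA material. The guess only sets the displacement scale of the
#'   first force-driven solve; its stress field is invariant to `init_E`.
#' @param seed integer seed governing weight initialization.
#' @return an object of class `cannccm`.
#' @export
new_cannccm <- function(bounds, mpn_hidden = c(12, 12), sn_hidden = c(16, 16),
                        eps_scale = NA_real_, sig_scale = NA_real_,
                        init_E = 10, init_nu = 0.45, seed = 1L) {
  extent <- if (inherits(bounds, "autop_mesh")) bounds$extent else as.numeric(bounds)
  stopifnot(length(extent) == 3, all(extent > 0))
  rng <- rng_stream(seed)
  mpn <- mpn_init(mpn_hidden, eps_scale, sig_scale, rng, init_E, init_nu)
  sn <- sn_init(sn_hidden, extent, rng)
  structure(list(mpn = mpn, sn = sn, extent = extent,
                 meta = list(seed = as.integer(seed), passes = 0L, phase = "fresh")),
            class = "cannccm")
}

# a tiny counter-based deterministic RNG wrapper so model init never touches
# the global .Random.seed
rng_stream <- function(seed) {
  env <- new.env()
  env$state <- as.integer(seed)
  with_state <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(env$state)
    env$state <- as.integer((as.double(env$state) * 69069 + 1) %% .Machine$integer.max)
    expr()
  }
  env$draw <- function(n, r) with_state(function() stats::runif(n, -r, r))
  env$norm <- function(n, sd) with_state(function() stats::rnorm(n, 0, sd))
  env$sample <- function(x, size) with_state(function() sample(x, size))
  env
}

xavier <- function(nout, nin, rng) {
  matrix(rng$draw(nout * nin, sqrt(6 / (nin + nout))), nout, nin)
}

mpn_init <- function(hidden, eps_scale, sig_scale, rng, init_E = 10, init_nu = 0.45) {
  stopifnot(length(hidden) == 2)
  fixed <- !(is.na(eps_scale) || is.na(sig_scale))
  if (!fixed) {
    eps_scale <- 0.01                # provisional: typical strain magnitude
    sig_scale <- init_E * eps_scale  # so the initial guess is O(1)
  }
  # W3 starts at zero: the fresh model is exactly its linear starting guess
  # and the tanh correction path only grows as the data demand it
  list(W1 = xavier(hidden[1], 6, rng), b1 = rep(0, hidden[1]),
       W2 = xavier(hidden[2], hidden[1], rng), b2 = rep(0, hidden[2]),
       W3 = matrix(0, 6, hidden[2]),
       A = iso_stiffness(init_E, init_nu) * eps_scale / sig_scale,
       A0 = iso_stiffness(init_E, init_nu) * eps_scale / sig_scale,
       eps_scale = eps_scale, sig_scale = sig_scale, scales_fixed = fixed)
}

sn_init <- function(hidden, extent, rng) {
  stopifnot(length(hidden) == 2)
  list(V1 = xavier(hidden[1], 3, rng), c1 = rep(0, hidden[1]),
       V2 = xavier(hidden[2], hidden[1], rng), c2 = rep(0, hidden[2]),
       v3 = matrix(0, 1, hidden[2]), c3 = 0,
       center = extent / 2, halfw = extent / 2)
}

#' Construct a CaNNCM encoding a homogeneous isotropic linear material
#'
#' The linear skip term of the MPN is set to the isotropic stiffness for
#' `(E, nu)` and the tanh path is silenced, so the model's stress response
#' and Jacobian are exactly linear-elastic. Useful as a known-truth model
#' and as the starting point of "what-if" experiments.
#'
#' @inheritParams new_cannccm
#' @param E Young's modulus (kPa).
#' @param nu Poisson's ratio.
#' @export
cannccm_linear_isotropic <- function(bounds, E, nu = 0.45, seed = 1L) {
  m <- new_cannccm(bounds, eps_scale = 1, sig_scale = 1, seed = seed)
  m$mpn$W3[] <- 0
  m$mpn$A <- iso_stiffness(E, nu)
  m$mpn$A0 <- m$mpn$A
  m$meta$phase <- "analytic"
  m
}

softplus <- function(a) ifelse(a > 30, a, log1p(exp(a)))

# ---- forward passes -------------------------------------------------------

sn_forward <- function(sn, x, cache = FALSE, Xn = NULL) {
  if (is.null(Xn)) {
    x <- rbind(x)
    Xn <- sweep(sweep(x, 2, sn$center), 2, sn$halfw, "/")
  }
  n <- nrow(Xn)
  H1 <- tanh(tcrossprod(Xn, sn$V1) + rep(sn$c1, each = n))
  H2 <- tanh(tcrossprod(H1, sn$V2) + rep(sn$c2, each = n))
  a <- as.numeric(tcrossprod(H2, sn$v3)) + sn$c3
  S <- softplus(a) / log(2)
  if (cache) list(S = S, a = a, H1 = H1, H2 = H2, Xn = Xn) else S
}

#' Spatial strain scale factors
#'
#' @param model a `cannccm`.
#' @param x positions, n x 3 matrix (mm).
#' @return positive scale factors S(x), length n.
#' @export
sn_scale <- function(model, x) sn_forward(model$sn, x)

# MPN on pre-scaled, normalized strain rows Z; returns normalized stress
mpn_forward_z <- function(mpn, Z, cache = FALSE) {
  n <- nrow(Z)
  H1 <- tanh(tcrossprod(Z, mpn$W1) + rep(mpn$b1, each = n))
  H2 <- tanh(tcrossprod(H1, mpn$W2) + rep(mpn$b2, each = n))
  h1_0 <- tanh(mpn$b1)
  h2_0 <- tanh(as.numeric(mpn$W2 %*% h1_0) + mpn$b2)
  out0 <- as.numeric(mpn$W3 %*% h2_0)
  out <- tcrossprod(H2, mpn$W3) + tcrossprod(Z, mpn$A) - rep(out0, each = n)
  if (cache) list(out = out, H1 = H1, H2 = H2, h1_0 = h1_0, h2_0 = h2_0) else out
}

check_in_bounds <- function(model, x) {
  x <- rbind(x)
  lo <- -1e-9; hi <- rep(1, 3)
  ok <- x[, 1] >= lo & x[, 2] >= lo & x[, 3] >= lo &
    x[, 1] <= model$extent[1] + 1e-9 & x[, 2] <= model$extent[2] + 1e-9 &
    x[, 3] <= model$extent[3] + 1e-9
  if (!all(ok)) stop("position outside the modeled volume")
  x
}

#' Evaluate the CaNNCM stress response
#'
#' @param model a `cannccm` with normalization constants set.
#' @param x position(s), vector of 3 or n x 3 matrix (mm); must lie inside
#'   the modeled volume.
#' @param eps Voigt strain, vector of 6 or n x 6 matrix.
#' @return Voigt stress (kPa), n x 6 matrix.
#' @export
cannccm_stress <- function(model, x, eps) {
  x <- check_in_bounds(model, x)
  eps <- rbind(eps)
  stopifnot(ncol(eps) == 6, nrow(eps) == nrow(x), all(is.finite(eps)))
  scales_ready(model)
  S <- sn_forward(model$sn, x)
  Z <- (eps * S) / model$mpn$eps_scale
  mpn_forward_z(model$mpn, Z) * model$mpn$sig_scale
}

scales_ready <- function(model) {
  if (is.na(model$mpn$eps_scale) || is.na(model$mpn$sig_scale))
    stop("model normalization constants are unset; train the MPN first or set eps_scale/sig_scale")
  invisible(TRUE)
}

# d(normalized out)/dZ at one normalized input z (6x6)
mpn_jac_z <- function(mpn, z) {
  h1 <- tanh(as.numeric(mpn$W1 %*% z) + mpn$b1)
  h2 <- tanh(as.numeric(mpn$W2 %*% h1) + mpn$b2)
  mpn$W3 %*% ((1 - h2^2) * (mpn$W2 %*% ((1 - h1^2) * mpn$W1))) + mpn$A
}

#' Material Jacobian of the CaNNCM
#'
#' The 6x6 tangent stiffness `d sigma / d eps` at `(x, eps)`, including the
#' S(x) chain factor, symmetrized as `(D + t(D))/2` and (optionally)
#' projected onto the SPD cone by flooring its eigenvalues before use in
#' stiffness assembly.
#'
#' @inheritParams cannccm_stress
#' @param eps Voigt strain (6-vector) at which to take the tangent.
#' @param symmetrize,spd_floor symmetrization / eigenvalue floor (relative
#'   to the largest eigenvalue). `spd_floor = NULL` skips the projection.
#' @return 6x6 stiffness (kPa).
#' @export
material_jacobian <- function(model, x, eps = rep(0, 6), symmetrize = TRUE,
                              spd_floor = 1e-6) {
  x <- check_in_bounds(model, x)
  stopifnot(nrow(x) == 1, length(eps) == 6)
  scales_ready(model)
  S <- sn_forward(model$sn, x)
  z <- as.numeric(eps) * S / model$mpn$eps_scale
  D <- S * (model$mpn$sig_scale / model$mpn$eps_scale) * mpn_jac_z(model$mpn, z)
  if (!all(is.finite(D))) stop("non-finite material Jacobian: model state is invalid")
  if (symmetrize) D <- (D + t(D)) / 2
  if (!is.null(spd_floor)) D <- spd_project(D, spd_floor)
  D
}

spd_project <- function(D, floor_frac = 1e-6) {
  e <- eigen((D + t(D)) / 2, symmetric = TRUE)
  fl <- max(abs(e$values)) * floor_frac
  if (fl <= 0) fl <- floor_frac
  v <- pmax(e$values, fl)
  e$vectors %*% (v * t(e$vectors))
}

# Shared base stiffness about zero strain (kPa); D(x) = S(x) * this.
# Evaluated as a symmetric secant over the reference strain scale
# (column k = [sigma(+h e_k) - sigma(-h e_k)] / 2h with h = eps_scale)
# rather than the pointwise derivative at 0: the secant samples the strain
# range the MPN was actually trained on, so it is robust to curvature the
# data do not constrain, and it coincides with the analytic Jacobian for
# linear responses.
mpn_tangent0 <- function(model, spd_floor = 1e-6) {
  scales_ready(model)
  mpn <- model$mpn
  Zp <- diag(6); Zm <- -Zp
  D <- (mpn$sig_scale / mpn$eps_scale) *
    t(mpn_forward_z(mpn, Zp) - mpn_forward_z(mpn, Zm)) / 2
  D <- (D + t(D)) / 2
  if (is.null(spd_floor)) D else spd_project(D, spd_floor)
}

#' Solver material from a CaNNCM
#'
#' Tangent stiffness at zero strain per integration point:
#' `D(x) = S(x) * D_tan`, the form consumed by [fem_solve()].
#' @param model a `cannccm`.
#' @param mesh an `autop_mesh`.
#' @export
cannccm_material <- function(model, mesh) {
  material_scaled(mpn_tangent0(model), sn_forward(model$sn, mesh$ip_coords))
}

#' Probe the Young's modulus encoded at a position
#'
#' Performs a virtual uniaxial-stress test on the model tangent: the 6x6
#' Jacobian at a reference strain is inverted to a compliance `C` and
#' `E = 1 / C[2, 2]` (the axial, y entry) is returned. A singular tangent
#' yields `NA` rather than a fabricated value.
#'
#' @param model a `cannccm`.
#' @param x positions, n x 3 matrix or 3-vector (mm).
#' @param eps_ref reference strain for the tangent (default zero).
#' @return Young's modulus E (kPa), length n.
#' @export
probe_youngs_modulus <- function(model, x, eps_ref = rep(0, 6)) {
  x <- check_in_bounds(model, x)
  if (all(eps_ref == 0)) {
    Dt <- mpn_tangent0(model, spd_floor = NULL)
    ev <- eigen(Dt, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) return(rep(NA_real_, nrow(x)))  # flagged, not fabricated
    Ct <- solve(Dt)
    as.numeric(sn_forward(model$sn, x)) / Ct[2, 2]
  } else {
    vapply(seq_len(nrow(x)), function(i) {
      D <- material_jacobian(model, x[i, ], eps_ref)
      C <- tryCatch(solve(D), error = function(e) NULL)
      if (is.null(C)) NA_real_ else 1 / C[2, 2]
    }, numeric(1))
  }
}

#' @export
print.cannccm <- function(x, ...) {
  cat(sprintf("<cannccm> MPN %s | SN %s | volume %s mm | passes %d (%s)\n",
              paste(dim(x$mpn$W1)[1], dim(x$mpn$W2)[1], sep = "x"),
              paste(dim(x$sn$V1)[1], dim(x$sn$V2)[1], sep = "x"),
              paste(x$extent, collapse = "x"),
              x$meta$passes, x$meta$phase))
  invisible(x)
}

#' @export
glance.cannccm <- function(x, ...) {
  np <- function(l) sum(vapply(l, length, 1L))
  tibble::tibble(
    mpn_params = np(x$mpn[c("W1", "b1", "W2", "b2", "W3", "A")]),
    sn_params = np(x$sn[c("V1", "c1", "V2", "c2", "v3", "c3")]),
    eps_scale = x$mpn$eps_scale, sig_scale = x$mpn$sig_scale,
    passes = x$meta$passes, phase = x$meta$phase)
}
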