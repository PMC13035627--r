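# Shared fixtures, built in code and cached for the test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# 8 mm cube, 2x2x2 elements: the smallest mesh with an interior node
tiny_mesh <- function() cached("tiny_mesh", build_hex_mesh(c(8, 8, 8), 4))

# 16 mm cube with a single 5 mm stiff sphere: cheap heterogeneous phantom
small_phantom <- function() cached("small_phantom", phantom_spec(
  c(16, 16, 16), 7.9,
  list(list(shape = "sphere", center = c(8, 8, 8), radii = 5, E = 19.8))))

small_mesh <- function() cached("small_mesh", build_hex_mesh(c(16, 16, 16), 4))

# forward-simulated single plane on the small phantom (exact measurements)
small_sim <- function() cached("small_sim", {
  mesh <- small_mesh()
  meas <- simulate_plane(small_phantom(), mesh, list(center_z = 8),
                         protocol = list(n_steps = 3, step_mm = 0.25))
  list(mesh = mesh, phantom = small_phantom(), measurements = meas)
})

# homogeneous desk fixture simulation (32 mm cube, one plane)
homog_sim <- function() cached("homog_sim", simulate_fixture(standard_fixtures("homogeneous_desk")))

# uniaxial compression BCs: top face displaced axially, bottom rollers,
# minimal lateral pins; the classic closed-form test state
uniaxial_bcs <- function(mesh, u_top) {
  top <- mesh_face_nodes(mesh, "ymax")
  bot <- mesh_face_nodes(mesh, "ymin")
  c1 <- which(rowSums(abs(mesh$nodes)) == 0)
  c2 <- which(mesh$nodes[, 1] == mesh$extent[1] &
                mesh$nodes[, 2] == 0 & mesh$nodes[, 3] == 0)
  fixed <- rbind(
    data.frame(node = bot, axis = 2, value = 0),
    data.frame(node = top, axis = 2, value = u_top),
    data.frame(node = c1, axis = 1, value = 0),
    data.frame(node = c1, axis = 3, value = 0),
    data.frame(node = c2, axis = 3, value = 0))
  bc_set(fixed = fixed, footprint = top)
}

# all-boundary-node prescription of a linear displacement field
linear_field_bcs <- function(mesh, a, G) {
  on_bnd <- apply(mesh$nodes, 1, function(p)
    any(abs(p) < 1e-9) || any(abs(p - mesh$extent) < 1e-9))
  bnd <- which(on_bnd)
  u <- t(a + G %*% t(mesh$nodes[bnd, , drop = FALSE]))
  fixed <- do.call(rbind, lapply(1:3, function(ax)
    data.frame(node = bnd, axis = ax, value = u[, ax])))
  bc_set(fixed = fixed)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected)) / max(abs(expected)), tol)
}
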