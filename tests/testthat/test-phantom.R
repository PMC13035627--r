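test_that("material fields place the right modulus at the right points", {
  fx <- standard_fixtures("two_sphere_desk")
  expect_equal(material_field(fx$phantom, rbind(c(11, 16, 12))), 19.8)
  expect_equal(material_field(fx$phantom, rbind(c(2, 2, 2))), 7.9)
  # sphere volume fraction approximates 4/3 pi r^3 under mesh quadrature
  full <- standard_fixtures("two_sphere_full")
  mesh <- build_hex_mesh(c(50, 50, 50), 2)
  E <- material_field(full$phantom, mesh)
  vol_per_ip <- 2^3 / 8
  vol_est <- sum(E > 10) * vol_per_ip / 2      # two identical spheres
  vol_true <- 4 / 3 * pi * 7.5^3
  expect_lt(abs(vol_est - vol_true) / vol_true, 0.05)
})

test_that("phantom specs validate and round-trip through YAML", {
  expect_error(phantom_spec(c(32, 32, 32), 7.9, nu = 0.6), "nu")
  expect_error(phantom_spec(c(32, 32, 32), 7.9, list(
    list(shape = "sphere", center = c(2, 2, 2), radii = 5, E = 19.8))),
    "outside")
  ph <- small_phantom()
  path <- tempfile(fileext = ".yaml")
  phantom_save_yaml(ph, path)
  back <- phantom_load_yaml(path)
  expect_equal(back$extent, ph$extent)
  expect_equal(back$inclusions[[1]]$E, 19.8)
})

test_that("homogeneous phantoms respond linearly across load steps", {
  sim <- homog_sim()
  p <- sim$measurements$planes[[1]]
  f <- vapply(p$steps, function(s) s$f, numeric(1))
  u <- vapply(p$steps, function(s) s$u, numeric(1))
  expect_rel_equal(f, f[1] / u[1] * u, 1e-8)
  # reaction force strictly positive and increasing with compression
  expect_true(all(f > 0))
  expect_true(all(diff(f) > 0))
})

test_that("exact measurements close the loop through the displacement FEA", {
  sim <- small_sim()
  mat <- phantom_material(sim$phantom, sim$mesh)
  p <- sim$measurements$planes[[1]]
  st <- p$steps[[2]]
  bot <- mesh_face_nodes(sim$mesh, "ymin")
  fixed <- rbind(
    data.frame(node = rep(bot, each = 3), axis = rep(1:3, length(bot)), value = 0),
    data.frame(node = p$footprint_nodes, axis = 2, value = -st$u))
  fwd <- fem_solve(sim$mesh, mat, bc_set(fixed = fixed, footprint = p$footprint_nodes))
  # feeding the recorded displacements back in reproduces the forward field
  keep <- !(p$measured_nodes %in% p$footprint_nodes)
  fixed2 <- rbind(fixed,
                  data.frame(node = p$measured_nodes[keep], axis = 2,
                             value = st$uy[keep]))
  dof <- 3L * (fixed2$node - 1L) + fixed2$axis
  fixed2 <- fixed2[!duplicated(dof), ]
  back <- fem_solve(sim$mesh, mat, bc_set(fixed = fixed2, footprint = p$footprint_nodes))
  expect_rel_equal(back$strain, fwd$strain, 1e-9)
})

test_that("mirrored phantoms produce mirrored measured displacements", {
  mesh <- small_mesh()
  ph1 <- phantom_spec(c(16, 16, 16), 7.9,
                      list(list(shape = "sphere", center = c(5, 8, 8), radii = 4, E = 19.8)))
  ph2 <- phantom_spec(c(16, 16, 16), 7.9,
                      list(list(shape = "sphere", center = c(11, 8, 8), radii = 4, E = 19.8)))
  m1 <- simulate_plane(ph1, mesh, list(center_z = 8))
  m2 <- simulate_plane(ph2, mesh, list(center_z = 8))
  p1 <- m1$planes[[1]]; p2 <- m2$planes[[1]]
  xs <- mesh$nodes[p1$measured_nodes, , drop = FALSE]
  key <- function(p) paste(round(p[, 1], 9), round(p[, 2], 9), round(p[, 3], 9))
  mirrored <- xs; mirrored[, 1] <- 16 - mirrored[, 1]
  idx <- match(key(mirrored), key(mesh$nodes[p2$measured_nodes, , drop = FALSE]))
  expect_false(anyNA(idx))
  expect_rel_equal(p2$steps[[3]]$uy[idx], p1$steps[[3]]$uy, 1e-9)
  expect_equal(p1$steps[[3]]$f, p2$steps[[3]]$f, tolerance = 1e-9)
})

test_that("the error model corrupts reproducibly and only where asked", {
  sim <- small_sim()
  mesh <- sim$mesh
  clean <- sim$measurements
  # zero amplitudes: identity
  same <- corrupt(clean, error_model(0, noise_sd = 0), mesh)
  expect_identical(same, clean)
  # pure bias: exact offset pattern, f and u untouched
  biased <- corrupt(clean, error_model(bias_amplitude = 0.05), mesh)
  for (k in 1:3) {
    expect_equal(biased$planes[[1]]$steps[[k]]$uy,
                 clean$planes[[1]]$steps[[k]]$uy + 0.05, tolerance = 1e-15)
    expect_identical(biased$planes[[1]]$steps[[k]]$f, clean$planes[[1]]$steps[[k]]$f)
  }
  # seeded noise: identical across calls, different for different seeds
  n1 <- corrupt(clean, error_model(noise_sd = 0.01, seed = 7), mesh)
  n2 <- corrupt(clean, error_model(noise_sd = 0.01, seed = 7), mesh)
  n3 <- corrupt(clean, error_model(noise_sd = 0.01, seed = 8), mesh)
  expect_identical(n1$planes[[1]]$steps[[1]]$uy, n2$planes[[1]]$steps[[1]]$uy)
  expect_false(identical(n1$planes[[1]]$steps[[1]]$uy, n3$planes[[1]]$steps[[1]]$uy))
})

test_that("standard fixtures are catalogued and consistent", {
  full <- standard_fixtures("two_sphere_full")
  expect_length(full$poses, 7)
  expect_equal(full$element_size, 2)
  desk <- standard_fixtures("two_sphere_desk")
  expect_length(desk$poses, 3)
  expect_error(standard_fixtures("nope"), "two_sphere_full")
})

test_that("a desk-scale plane simulates quickly end to end", {
  t0 <- Sys.time()
  fx <- standard_fixtures("two_sphere_desk")
  mesh <- build_hex_mesh(fx$phantom$extent, fx$element_size)
  meas <- simulate_plane(fx$phantom, mesh, fx$poses[[1]],
                         list(n_steps = 1, step_mm = 0.5), fx$footprint)
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 5)
  expect_gt(meas$planes[[1]]$steps[[1]]$f, 0)
})

test_that("measurement containers round-trip through JSON", {
  sim <- small_sim()
  path <- tempfile(fileext = ".json")
  measurements_save(sim$measurements, path)
  back <- measurements_load(path)
  p0 <- sim$measurements$planes[[1]]; p1 <- back$planes[[1]]
  expect_identical(p1$plane_id, p0$plane_id)
  expect_identical(p1$footprint_nodes, p0$footprint_nodes)
  expect_identical(p1$steps[[2]]$uy, p0$steps[[2]]$uy)
  expect_equal(p1$steps[[2]]$f, p0$steps[[2]]$f)
  # full-field mode carries all three components at every node
  ff <- simulate_plane(small_phantom(), small_mesh(), list(center_z = 8),
                       protocol = list(n_steps = 1, step_mm = 0.25),
                       full_field = TRUE)
  expect_identical(ff$planes[[1]]$measured_nodes, seq_len(small_mesh()$n_nodes))
  expect_identical(dim(ff$planes[[1]]$steps[[1]]$u3), c(small_mesh()$n_nodes, 3L))
  path2 <- tempfile(fileext = ".json")
  measurements_save(ff, path2)
  back2 <- measurements_load(path2)
  expect_identical(back2$planes[[1]]$steps[[1]]$u3, ff$planes[[1]]$steps[[1]]$u3)
})
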