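test_that("a linear isotropic model encodes its material exactly", {
  m <- tiny_mesh()
  mod <- cannccm_linear_isotropic(m, 7.9, 0.45)
  x <- c(4, 4, 4)
  # stress response is the closed-form isotropic law
  eps <- c(-0.01, 0.02, 0, 0.005, 0, -0.003)
  expect_equal(as.numeric(cannccm_stress(mod, x, eps)),
               as.numeric(iso_stiffness(7.9, 0.45) %*% eps), tolerance = 1e-12)
  # Jacobian is the isotropic stiffness matrix exactly
  D <- material_jacobian(mod, x, rep(0, 6), spd_floor = NULL)
  expect_equal(D, iso_stiffness(7.9, 0.45), tolerance = 1e-12)
  # probed modulus: background value, and scaled by S = 19.8/7.9 at a point
  expect_equal(probe_youngs_modulus(mod, x), 7.9, tolerance = 1e-9)
  mod2 <- mod
  mod2$sn$c3 <- log(expm1(19.8 / 7.9 * log(2)))   # softplus^-1 of target
  expect_equal(probe_youngs_modulus(mod2, x), 19.8, tolerance = 1e-6)
  # zero strain maps to exactly zero stress
  expect_identical(as.numeric(cannccm_stress(mod, x, rep(0, 6))), rep(0, 6))
})

test_that("scale factors act linearly through a linear MPN", {
  m <- tiny_mesh()
  mod <- cannccm_linear_isotropic(m, 10, 0.4)
  x <- c(2, 6, 4)
  eps <- c(0.01, -0.004, 0.002, 0.001, 0, 0.003)
  s1 <- cannccm_stress(mod, x, eps)
  mod$sn$c3 <- log(expm1(2 * log(2)))   # force S = 2 everywhere
  expect_equal(sn_scale(mod, rbind(x)), 2, tolerance = 1e-12)
  expect_equal(as.numeric(cannccm_stress(mod, x, eps)), 2 * as.numeric(s1),
               tolerance = 1e-12)
  D2 <- material_jacobian(mod, x, rep(0, 6), spd_floor = NULL)
  expect_equal(D2, 2 * iso_stiffness(10, 0.4), tolerance = 1e-12)
})

test_that("fresh models are spatially homogeneous with S = 1 everywhere", {
  m <- small_mesh()
  mod <- new_cannccm(m, seed = 7)
  S <- sn_scale(mod, m$ip_coords)
  expect_equal(S, rep(1, m$n_ip), tolerance = 1e-6)
  E <- probe_youngs_modulus(mod, m$ip_coords)
  expect_lt(diff(range(E)), 1e-6 * mean(E))
  expect_error(cannccm_stress(mod, c(100, 0, 0), rep(0, 6)), "outside")
})

test_that("analytic Jacobian matches central finite differences", {
  m <- small_mesh()
  mod <- new_cannccm(m, eps_scale = 0.01, sig_scale = 0.1, seed = 42)
  # give the tanh path real weight so the check is not trivially linear
  mod$mpn$W3 <- matrix(seq(-0.3, 0.3, length.out = length(mod$mpn$W3)), 6)
  set.seed(3)
  for (trial in 1:3) {
    x0 <- runif(3, 2, 14)
    e0 <- runif(6, -0.005, 0.005)
    Dan <- material_jacobian(mod, x0, e0, symmetrize = FALSE, spd_floor = NULL)
    h <- 1e-6
    Dfd <- matrix(0, 6, 6)
    for (k in 1:6) {
      ep <- e0; em <- e0
      ep[k] <- ep[k] + h; em[k] <- em[k] - h
      Dfd[, k] <- (cannccm_stress(mod, x0, ep) - cannccm_stress(mod, x0, em)) / (2 * h)
    }
    expect_lt(max(abs(Dan - Dfd)) / max(abs(Dfd)), 1e-5)
  }
})

test_that("SPD projection floors the Jacobian spectrum", {
  m <- tiny_mesh()
  mod <- cannccm_linear_isotropic(m, 10, 0.3)
  D <- material_jacobian(mod, c(4, 4, 4), rep(0, 6), spd_floor = 1e-6)
  ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev >= 1e-6 * max(ev) * 0.999))
  expect_equal(D, t(D))
})

test_that("MPN training recovers a homogeneous linear material", {
  m <- small_mesh()
  set.seed(11)
  eps <- matrix(runif(600 * 6, -0.01, 0.01), ncol = 6)
  sigma <- eps %*% t(iso_stiffness(10, 0.45))
  mod <- new_cannccm(m, seed = 5)
  mod <- train_mpn(mod, eps, sigma,
                   control = train_control(epochs = 1500, lr = 0.02,
                                           target_rel_rms = 0.005))
  E <- probe_youngs_modulus(mod, c(8, 8, 8))
  expect_equal(E, 10, tolerance = 0.02)
})

test_that("an MPN trained on mixed materials responds between the pure laws", {
  m <- small_mesh()
  set.seed(12)
  eps <- matrix(runif(800 * 6, -0.01, 0.01), ncol = 6)
  D1 <- iso_stiffness(6, 0.45); D2 <- iso_stiffness(18, 0.45)
  sigma <- rbind(eps[1:400, ] %*% t(D1), eps[401:800, ] %*% t(D2))
  mod <- new_cannccm(m, seed = 6)
  mod <- train_mpn(mod, eps, sigma,
                   control = train_control(epochs = 1500, target_rel_rms = 0.01))
  e_test <- c(-0.008, 0.01, 0.002, 0, 0.004, 0)
  s_hat <- as.numeric(cannccm_stress(mod, c(8, 8, 8), e_test))
  s1 <- as.numeric(D1 %*% e_test); s2 <- as.numeric(D2 %*% e_test)
  lo <- pmin(s1, s2) - 0.02 * max(abs(c(s1, s2)))
  hi <- pmax(s1, s2) + 0.02 * max(abs(c(s1, s2)))
  expect_true(all(s_hat >= lo & s_hat <= hi))
})

test_that("all-zero training pairs change nothing (structural zero anchor)", {
  m <- tiny_mesh()
  mod <- new_cannccm(m, eps_scale = 0.01, sig_scale = 0.1, seed = 9)
  before <- mod$mpn[c("W1", "b1", "W2", "b2", "W3", "A")]
  mod2 <- train_mpn(mod, matrix(0, 50, 6), matrix(0, 50, 6),
                    control = train_control(epochs = 50))
  after <- mod2$mpn[c("W1", "b1", "W2", "b2", "W3", "A")]
  for (k in names(before)) expect_equal(after[[k]], before[[k]], tolerance = 1e-12)
})

test_that("SN training is a no-op when the data already match", {
  m <- small_mesh()
  mod <- cannccm_linear_isotropic(m, 7.9, 0.45)
  set.seed(13)
  n <- m$n_ip
  eps <- matrix(runif(n * 6, -0.01, 0.01), ncol = 6)
  sigma <- eps %*% t(iso_stiffness(7.9, 0.45))
  mod2 <- train_sn(mod, m$ip_coords, eps, sigma,
                   control = train_control(epochs = 150, target_rel_rms = 1e-4))
  S <- sn_scale(mod2, m$ip_coords)
  expect_true(all(abs(S - 1) <= 0.05))
})

test_that("SN training solves a constructed subregion inverse problem", {
  m <- small_mesh()
  mod <- cannccm_linear_isotropic(m, 7.9, 0.45)
  set.seed(14)
  n <- m$n_ip
  eps <- matrix(runif(n * 6, -0.01, 0.01), ncol = 6)
  inside <- material_field(small_phantom(), m) > 10   # the sphere region
  S_true <- ifelse(inside, 2, 1)
  sigma <- (eps * S_true) %*% t(iso_stiffness(7.9, 0.45))
  mod2 <- train_sn(mod, m$ip_coords, eps, sigma,
                   control = train_control(epochs = 2000, lr = 0.03,
                                           target_rel_rms = 0.01))
  S <- sn_scale(mod2, m$ip_coords)
  ctr <- which.min(rowSums(sweep(m$ip_coords, 2, c(8, 8, 8))^2))
  expect_equal(S[ctr], 2, tolerance = 0.15)
  expect_equal(mean(S[!inside & rowSums(sweep(m$ip_coords, 2, c(8, 8, 8))^2) > 49]),
               1, tolerance = 0.1)
})

test_that("zero weights outside a region limit SN changes there", {
  m <- small_mesh()
  mod <- cannccm_linear_isotropic(m, 7.9, 0.45)
  set.seed(15)
  n <- m$n_ip
  eps <- matrix(runif(n * 6, -0.01, 0.01), ncol = 6)
  sigma <- (eps * 1.8) %*% t(iso_stiffness(7.9, 0.45))  # all data say S = 1.8
  w <- as.numeric(m$ip_coords[, 3] <= 8)                # but only z <= 8 counts
  mod2 <- train_sn(mod, m$ip_coords, eps, sigma, weights = w,
                   control = train_control(epochs = 300, target_rel_rms = 0.01))
  S <- sn_scale(mod2, m$ip_coords)
  drift_in <- mean(abs(S[w == 1] - 1))
  drift_out <- mean(abs(S[m$ip_coords[, 3] > 12] - 1))
  expect_gt(drift_in, drift_out)
  expect_error(train_sn(mod, m$ip_coords, eps, sigma, weights = rep(0, n)),
               "zero")
})

test_that("probe agrees with a uniaxial stress-strain fitting oracle", {
  m <- tiny_mesh()
  mod <- cannccm_linear_isotropic(m, 12.5, 0.42)
  x <- c(4, 4, 4)
  # oracle: find the strain state giving uniaxial stress via Newton on the
  # stress response alone, then fit E as the axial slope
  target <- 0.01  # kPa axial stress
  eps <- rep(0, 6)
  for (it in 1:30) {
    s <- as.numeric(cannccm_stress(mod, x, eps))
    r <- s - c(0, target, 0, 0, 0, 0)
    if (max(abs(r)) < 1e-13) break
    J <- matrix(0, 6, 6)
    h <- 1e-7
    for (k in 1:6) {
      e2 <- eps; e2[k] <- e2[k] + h
      J[, k] <- (as.numeric(cannccm_stress(mod, x, e2)) - s) / h
    }
    eps <- eps - solve(J, r)
  }
  E_oracle <- target / eps[2]
  expect_equal(probe_youngs_modulus(mod, x), E_oracle, tolerance = 1e-6)
})

test_that("checkpoints round-trip bit-identically", {
  m <- small_mesh()
  mod <- new_cannccm(m, seed = 21)
  set.seed(22)
  eps <- matrix(runif(200 * 6, -0.01, 0.01), ncol = 6)
  sigma <- eps %*% t(iso_stiffness(9, 0.45))
  mod <- train_mpn(mod, eps, sigma, control = train_control(epochs = 60))
  mod <- train_sn(mod, m$ip_coords[1:200, ], eps, sigma,
                  control = train_control(epochs = 40))
  path <- tempfile(fileext = ".json")
  cannccm_save(mod, path)
  back <- cannccm_load(path)
  for (k in c("W1", "b1", "W2", "b2", "W3", "A"))
    expect_identical(back$mpn[[k]], mod$mpn[[k]])
  for (k in c("V1", "c1", "V2", "c2", "v3"))
    expect_identical(back$sn[[k]], mod$sn[[k]])
  x <- m$ip_coords[seq(1, m$n_ip, by = 37), ]
  expect_identical(probe_youngs_modulus(back, x), probe_youngs_modulus(mod, x))
})

test_that("training is exactly reproducible for a fixed seed", {
  m <- small_mesh()
  set.seed(30)
  eps <- matrix(runif(300 * 6, -0.01, 0.01), ncol = 6)
  sigma <- eps %*% t(iso_stiffness(8, 0.45))
  run <- function() {
    mod <- new_cannccm(m, seed = 99)
    mod <- train_mpn(mod, eps, sigma, control = train_control(epochs = 80))
    train_sn(mod, m$ip_coords[1:300, ], eps, sigma,
             control = train_control(epochs = 50))
  }
  m1 <- run(); m2 <- run()
  expect_identical(m1$mpn, m2$mpn)
  expect_identical(m1$sn, m2$sn)
})

test_that("MPN/SN training errors are explicit", {
  m <- tiny_mesh()
  mod <- new_cannccm(m, seed = 1)
  expect_error(train_mpn(mod, matrix(0, 0, 6), matrix(0, 0, 6)), "no training pairs")
  expect_error(train_sn(mod, matrix(0, 0, 3), matrix(0, 0, 6), matrix(0, 0, 6)),
               "no training pairs")
})
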