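test_that("settling finds first contact for a plane above a flat insert", {
  blk <- flat_block(half = 6, height = 8, nx = 16L)
  punch <- tkrfem:::box_surface(c(-10, -10, 10), c(10, 10, 14))
  m <- contact_model(punch, foundation_model(blk, k_f = 100))
  u0 <- settle_to_contact(m, tol = 1e-6)
  expect_equal(u0, -2, tolerance = 1e-4)
})

test_that("a concentric condyle settles by exactly the apex gap", {
  gp <- synthetic_geom_params(resolution = 0.5)
  k <- small_knee(0.5)
  u0 <- settle_to_contact(k$model)
  # faceting of the condyle sphere shifts first contact by the chord sag
  expect_equal(u0, -gp$initial_gap, tolerance = 0.05)
})

test_that("pre-penetrating configurations are rejected with advice", {
  blk <- flat_block(half = 6, height = 8, nx = 12L)
  low <- tkrfem:::box_surface(c(-10, -10, 7), c(10, 10, 12))  # overlaps
  m <- contact_model(low, foundation_model(blk, k_f = 100))
  expect_error(settle_to_contact(m), "interpenetrat")
  expect_error(solve_timestep(m, 0, 100), "interpenetrat")
})

test_that("flat punch: uniform pressure Fz/A and penetration Fz/(k A)", {
  kf <- 100; Fz <- 500
  blk <- flat_block(half = 6, height = 8, nx = 24L)
  punch <- tkrfem:::box_surface(c(-10, -10, 10), c(10, 10, 14))
  fnd <- foundation_model(blk, k_f = kf)
  m <- contact_model(punch, fnd)
  sol <- solve_timestep(m, 0, Fz, 0)
  A <- sum(fnd$areas)
  p <- sol$field$pressure[sol$field$pressure > 0]
  expect_equal(max(p), Fz / A, tolerance = 1e-6)
  expect_equal(min(p), Fz / A, tolerance = 1e-6)       # uniform
  expect_equal(max(sol$field$pressure) / kf, Fz / (kf * A),
               tolerance = 1e-6)
  expect_equal(sol$field$total_force, Fz, tolerance = 1e-6 * Fz)
  expect_equal(sol$field$cop, c(0, 0), tolerance = 1e-6)
})

test_that("a zero-force step carries zero pressure everywhere", {
  k <- small_knee(0.4)
  sol <- solve_timestep(k$model, 5, 0, 0)
  expect_equal(sol$field$pressure, rep(0, length(sol$field$pressure)))
  expect_equal(sol$field$total_force, 0)
})

test_that("symmetric model under zero moment stays mediolaterally balanced", {
  k <- small_knee(0.5)
  # mirror-symmetric ligament pair (equal stiffness) keeps the wrench even
  sym <- k$bundles
  sym$LCL <- ligament_bundle("LCL", k$bundles$MCL$origin * c(-1, 1, 1),
                             k$bundles$MCL$insertion * c(-1, 1, 1),
                             k = k$bundles$MCL$k,
                             eps_r = k$bundles$MCL$eps_r)
  m <- contact_model(k$geo$femoral_component, k$fnd, sym,
                     joint_center = k$jc)
  sol <- solve_timestep(m, 10, 1800, 0)
  expect_lt(abs(sol$pose$phi), 1e-6)
  share <- tkrfem:::medial_force_share(m, sol$field)
  expect_equal(share, 0.5, tolerance = 1e-3)
})

test_that("equilibrium is load-controlled: k_f rescaling keeps the force", {
  k <- small_knee(0.4)
  sol1 <- solve_timestep(k$model, 10, 1500, 500)
  fnd2 <- foundation_model(k$geo$tibial_insert, k_f = 2 * k$fnd$k_f)
  m2 <- contact_model(k$geo$femoral_component, fnd2, k$bundles,
                      joint_center = k$jc)
  sol2 <- solve_timestep(m2, 10, 1500, 500)
  expect_equal(sol2$field$total_force + tkrfem:::eval_contact_state(
    m2, 10, sol2$pose$u_z, sol2$pose$phi)$F_lig[3], 1500,
    tolerance = 1e-6 * 1500)
  expect_equal(sol1$field$total_force, sol2$field$total_force,
               tolerance = 2e-6 * sol1$field$total_force)
  expect_gt(sol2$field$max_pressure, sol1$field$max_pressure)
})

test_that("medial load share grows monotonically with varus moment", {
  k <- small_knee(0.4)
  # varus drive moment is negative about the +y (anterior) axis
  varus_moments <- seq(-6000, 6000, length.out = 7)
  shares <- vapply(varus_moments, function(mv) {
    sol <- solve_timestep(k$model, 10, 1800, -mv)
    tkrfem:::medial_force_share(k$model, sol$field)
  }, 0)
  expect_true(all(diff(shares) >= -1e-9))
  expect_gt(shares[7], shares[1])
})

test_that("gait runs converge at every sample with logged residuals", {
  k <- small_knee(0.4)
  bc <- synth_gait("normal", peak_force = 1800, n_points = 31L, seed = 3L)
  traj <- run_gait(k$model, bc)
  s <- traj$summary
  expect_equal(nrow(s), 31L)
  expect_true(all(abs(s$residual_force) <= 1e-6 * pmax(s$Fz_applied, 1)))
  expect_true(all(abs(s$residual_moment) <=
                    1e-6 * pmax(abs(s$My_applied), 1)))
  expect_true(all(s$max_pressure > 0))
  expect_length(traj$ligaments[[1]], 2L)
  expect_true(all(is.finite(unlist(traj$ligaments))))
})

test_that("peak metrics find the constructed force peaks", {
  k <- small_knee(0.4)
  bc <- synth_gait("normal", peak_force = 1800, n_points = 31L, seed = 3L)
  traj <- run_gait(k$model, bc)
  pk <- peak_metrics(traj, bc)
  expect_equal(pk$i1, which.max(bc$Fz[1:15]))
  expect_equal(pk$i2, 15L + which.max(bc$Fz[16:31]))
  expect_gt(pk$P1, 0)
  expect_gt(pk$P2, 0)
  expect_equal(pk$F1, traj$summary$total_force[pk$i1])
})

test_that("constant-force trials fall back to the 20%/80% indices", {
  blk <- flat_block(half = 6, height = 8, nx = 12L)
  punch <- tkrfem:::box_surface(c(-10, -10, 10), c(10, 10, 14))
  m <- contact_model(punch, foundation_model(blk, k_f = 100))
  bc <- gait_bc(seq(0, 1, length.out = 11), rep(0, 11), rep(300, 11),
                rep(0, 11), label = "constant")
  traj <- run_gait(m, bc)
  expect_warning(pk <- peak_metrics(traj, bc), "20%/80%")
  expect_equal(pk$i1, 3L)
  expect_equal(pk$i2, 9L)
  expect_equal(pk$P1, pk$P2)
  one <- traj; one$summary <- one$summary[1, ]
  expect_error(peak_metrics(one, bc), "fewer than 2")
})
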