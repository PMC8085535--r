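test_that("Lame constants follow the engineering-constant conversion", {
  u <- lame_from_engineering(1200, 0.46)          # UHMWPE
  expect_equal(u$G, 1200 / (2 * 1.46))
  expect_equal(u$lam, 2 * u$G * 0.46 / 0.08)
  expect_equal(round(u$G, 2), 410.96)
  expect_equal(round(u$lam, 2), 4726.03)

  c_ <- lame_from_engineering(210000, 0.3)        # CoCrMo
  expect_equal(round(c_$G, 2), 80769.23)
  expect_equal(round(c_$lam, 2), 121153.85)

  z <- lame_from_engineering(100, 0)
  expect_equal(z$G, 50)
  expect_equal(z$lam, 0)
  expect_error(lame_from_engineering(100, 0.5), "Poisson")
  expect_error(lame_from_engineering(-5, 0.3), "E")
})

test_that("strain energy vanishes only for rigid rotations", {
  m <- neo_hookean("unit", E = 2 * (1 + 0), v = 0)  # G = 1, lam = 0
  expect_equal(strain_energy(diag(3), m), 0)
  # pure dilation F = 1.1 I
  expect_equal(strain_energy(1.1 * diag(3), m),
               0.5 * (3 * 1.21 - 3) - log(1.331), tolerance = 1e-12)
  # simple shear: J = 1 so lam drops out
  Fs <- diag(3); Fs[1, 2] <- 0.2
  m2 <- neo_hookean("unit2", E = 2.9, v = 0.45)
  expect_equal(strain_energy(Fs, m) / m$G,
               strain_energy(Fs, m2) / m2$G, tolerance = 1e-12)
  expect_equal(strain_energy(Fs, m), 0.02, tolerance = 1e-12)
  # rotations carry zero energy
  R <- tkrfem:::rotation_matrix(c(1, 2, 3), 37)
  expect_equal(strain_energy(R, m), 0, tolerance = 1e-12)
  expect_error(strain_energy(-diag(3), m), "inverted")
})

test_that("frame indifference: energy is invariant to left rotations", {
  m <- neo_hookean("UHMWPE", 1200, 0.46)
  set.seed(7)
  for (i in 1:20) {
    F_ <- diag(3) + matrix(rnorm(9, sd = 0.05), 3, 3)
    if (det(F_) <= 0) next
    R <- tkrfem:::rotation_matrix(rnorm(3), runif(1, 0, 360))
    expect_equal(strain_energy(R %*% F_, m), strain_energy(F_, m),
                 tolerance = 1e-12)
  }
})

test_that("Cauchy stress closed forms and energy consistency", {
  m <- neo_hookean("UHMWPE", 1200, 0.46)
  expect_equal(cauchy_stress(diag(3), m), matrix(0, 3, 3))
  # simple shear at J = 1: sigma_12 = G * gamma
  Fs <- diag(3); Fs[1, 2] <- 0.1
  sig <- cauchy_stress(Fs, m)
  expect_equal(sig[1, 2], m$G * 0.1, tolerance = 1e-12)
  expect_equal(sig, t(sig))

  # finite-difference first Piola stress P = dPsi/dF, then
  # sigma = (1/J) P F^T — independent oracle for the closed form
  fd_cauchy <- function(F_, m, h = 1e-6) {
    P <- matrix(0, 3, 3)
    for (i in 1:3) for (j in 1:3) {
      Fp <- F_; Fp[i, j] <- Fp[i, j] + h
      Fm <- F_; Fm[i, j] <- Fm[i, j] - h
      P[i, j] <- (strain_energy(Fp, m) - strain_energy(Fm, m)) / (2 * h)
    }
    P %*% t(F_) / det(F_)
  }
  set.seed(11)
  n_ok <- 0L
  while (n_ok < 50L) {
    F_ <- diag(3) + matrix(rnorm(9, sd = 0.08), 3, 3)
    if (det(F_) < 0.8 || det(F_) > 1.2) next
    n_ok <- n_ok + 1L
    sig <- cauchy_stress(F_, m)
    expect_equal(sig, fd_cauchy(F_, m),
                 tolerance = 1e-6)
  }
})

test_that("the small-strain limit recovers isotropic linear elasticity", {
  for (mat in list(neo_hookean("UHMWPE", 1200, 0.46),
                   neo_hookean("CoCrMo", 210000, 0.3))) {
    eps <- 1e-5
    # uniaxial stress state: axial stretch with lateral Poisson contraction
    F_ <- diag(c(1 + eps, 1 - mat$v * eps, 1 - mat$v * eps))
    sig <- cauchy_stress(F_, mat)
    expect_equal(sig[1, 1] / eps, mat$E, tolerance = 0.01 * mat$E)
    expect_lt(abs(sig[2, 2]), abs(sig[1, 1]) * 0.01)
  }
})

test_that("the default material library carries the implant constants", {
  mats <- default_materials()
  expect_equal(mats$femoral_component$E, 210000)
  expect_equal(mats$femoral_component$v, 0.3)
  expect_equal(mats$tibial_insert$E, 1200)
  expect_equal(mats$tibial_insert$v, 0.46)
  for (nm in c("femur", "tibia", "fibula", "tibial_tray"))
    expect_s3_class(mats[[nm]], "rigid_material")
  expect_match(materials_to_yaml(mats), "UHMWPE")
})
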