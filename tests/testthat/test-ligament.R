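test_that("zero-load length follows L0 = Lr/(1 + eps_r)", {
  expect_equal(zero_load_length(60, 0.04), 60 / 1.04)   # 57.6923
  expect_equal(zero_load_length(50, 0), 50)
  expect_equal(zero_load_length(57, -0.05), 60)
  expect_error(zero_load_length(60, -1), "eps_r")
  expect_error(zero_load_length(0, 0.04), "L_r")
})

test_that("force law worked values hold for the MCL parameter set", {
  k <- 8250; eps_l <- 0.03
  expect_equal(ligament_force_strain(-0.01, k, eps_l), 0)
  expect_equal(ligament_force_strain(0.03, k, eps_l),
               0.25 * 8250 * 0.0009 / 0.03)              # 61.875
  expect_equal(ligament_force_strain(0.06, k, eps_l), 247.5)  # = k*eps_l
  expect_equal(ligament_force_strain(0.10, k, eps_l), 577.5)
})

test_that("the quadratic and linear branches join continuously at 2*eps_l", {
  set.seed(42)
  for (i in 1:100) {
    k <- runif(1, 100, 20000)
    eps_l <- runif(1, 0.005, 0.08)
    below <- 0.25 * k * (2 * eps_l)^2 / eps_l
    above <- k * (2 * eps_l - eps_l)
    expect_equal(below, above, tolerance = 1e-14)
    expect_equal(ligament_force_strain(2 * eps_l, k, eps_l), k * eps_l,
                 tolerance = 1e-14)
  }
})

test_that("the force law is non-decreasing and has slope k when linear", {
  k <- 6000; eps_l <- 0.03
  grid <- seq(-0.1, 0.3, length.out = 2000)
  f <- ligament_force_strain(grid, k, eps_l)
  expect_true(all(diff(f) >= 0))
  # finite-difference slope deep in the linear branch
  h <- 1e-7
  slope <- (ligament_force_strain(0.2 + h, k, eps_l) -
              ligament_force_strain(0.2 - h, k, eps_l)) / (2 * h)
  expect_equal(slope, k, tolerance = 1e-9 * k)
})

test_that("default bundles carry the collateral ligament parameters", {
  b <- make_default_bundles()
  expect_equal(b$MCL$k, 8250)
  expect_equal(b$MCL$eps_r, 0.04)
  expect_equal(b$LCL$k, 6000)
  expect_equal(b$LCL$eps_r, -0.05)
  # slack LCL: zero-load length exceeds the reference length
  expect_gt(b$LCL$L_0, b$LCL$L_r)
  expect_lt(b$MCL$L_0, b$MCL$L_r)
  expect_equal(b$MCL$L_0, b$MCL$L_r / 1.04, tolerance = 1e-12)
})

test_that("coincident attachment points are rejected", {
  expect_error(ligament_bundle("x", c(0, 0, 0), c(0, 0, 0), 1000, 0.04),
               "coincide")
})

test_that("attachment shifts translate both points and preserve lengths", {
  b <- make_default_bundles()$MCL
  shifted <- perturb_attachments(b, "proximal", 5)
  expect_equal(shifted$origin[3], b$origin[3] + 5)
  expect_equal(shifted$insertion[3], b$insertion[3] + 5)
  expect_identical(perturb_attachments(b, "anterior", 0), b)
  expect_error(perturb_attachments(b, "sideways", 5), "direction")

  for (seed in 1:8) {
    rb <- random_bundle(seed)
    d <- sample(c("anterior", "posterior", "medial", "lateral",
                  "proximal", "distal"), 1)
    out <- perturb_attachments(rb, d, runif(1, 0, 10))
    expect_equal(out$L_r, rb$L_r, tolerance = 1e-12)
    expect_equal(out$L_0, rb$L_0, tolerance = 1e-12)
  }
})

test_that("parameter scaling is multiplicative and recalibrates L0", {
  b <- make_default_bundles()$MCL
  expect_equal(scale_parameter(b, "eps_r", 5)$eps_r, 0.042)
  expect_equal(scale_parameter(b, "k", 10)$k, 9075)
  expect_identical(scale_parameter(b, "k", 0), b)
  b2 <- scale_parameter(b, "eps_r", 10)
  expect_equal(b2$L_r, b$L_r)                    # geometry untouched
  expect_equal(b2$L_0, b$L_r / (1 + 0.044), tolerance = 1e-12)
  slack <- ligament_bundle("s", c(0, 0, 0), c(0, 0, 60), 1000, -0.9)
  expect_error(scale_parameter(slack, "eps_r", 20), "-1")
})

test_that("ligament YAML serialization round-trips", {
  b <- make_default_bundles()
  txt <- ligaments_to_yaml(b)
  back <- ligaments_from_yaml(text = txt)
  expect_equal(back$MCL$k, b$MCL$k)
  expect_equal(back$LCL$eps_r, b$LCL$eps_r)
  expect_equal(back$MCL$L_0, b$MCL$L_0)
})
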