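write_sto <- function(lines, ext = ".sto") {
  path <- withr::local_tempfile(fileext = ext,
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("OpenSim storage tables parse with header checks", {
  path <- write_sto(c("knee_motion", "version=1", "nRows=3", "nColumns=2",
                      "inDegrees=yes", "endheader",
                      "time\tknee_angle", "0\t1.5", "0.1\t2.5", "0.2\t3.5"))
  tab <- read_motion_table(path)
  expect_equal(nrow(tab), 3L)
  expect_named(tab, c("time", "knee_angle"))
  expect_true(attr(tab, "in_degrees"))

  rad <- write_sto(c("nRows=2", "nColumns=2", "inDegrees=no", "endheader",
                     "time x", "0 1", "1 2"))
  expect_false(attr(read_motion_table(rad), "in_degrees"))

  bad <- write_sto(c("nRows=5", "nColumns=2", "endheader",
                     "time x", "0 1", "1 2", "2 3"))
  expect_error(read_motion_table(bad), "nRows=5.*3 rows")

  noh <- write_sto(c("time x", "0 1", "1 2"))
  expect_error(read_motion_table(noh), "endheader")
})

test_that("zero-phase low-pass keeps DC and the gait band, kills noise", {
  fs <- 120
  t <- seq(0, 4, by = 1 / fs)
  expect_equal(lowpass_filter(rep(3.7, 200), fs, 6), rep(3.7, 200))

  interior <- t > 1 & t < 3
  s1 <- sin(2 * pi * 1 * t)
  f1 <- lowpass_filter(s1, fs, 6)
  amp <- function(x) sqrt(2 * mean(x[interior]^2))
  expect_equal(amp(f1), amp(s1), tolerance = 0.02)

  s50 <- sin(2 * pi * 50 * t)
  f50 <- lowpass_filter(s50, fs, 6)
  expect_lt(amp(f50), 0.05 * amp(s50))

  expect_error(lowpass_filter(s1, fs, 60), "Nyquist")
})

test_that("synthetic gait places the two force peaks at 20% and 80% stance", {
  for (pattern in c("normal", "bouncy", "crouch", "smooth")) {
    for (seed in 1:20) {
      bc <- synth_gait(pattern, peak_force = 2000, n_points = 101L,
                       seed = seed)
      Fz <- bc$Fz
      maxima <- which(diff(sign(diff(Fz))) < 0) + 1L
      expect_length(maxima, 2L)
      expect_true(abs(maxima[1] - 21L) <= 2L,
                  label = sprintf("%s seed %d first peak at %d", pattern,
                                  seed, maxima[1]))
      expect_true(abs(maxima[2] - 81L) <= 2L,
                  label = sprintf("%s seed %d second peak at %d", pattern,
                                  seed, maxima[2]))
      expect_equal(max(Fz), 2000)
      expect_true(all(Fz >= 0))
    }
  }
})

test_that("synthetic gait is deterministic under a fixed seed", {
  a <- synth_gait("bouncy", 2600, 101L, seed = 7L)
  b <- synth_gait("bouncy", 2600, 101L, seed = 7L)
  expect_identical(a, b)
  c_ <- synth_gait("bouncy", 2600, 101L, seed = 8L)
  expect_false(identical(a$Fz, c_$Fz))
})

test_that("bouncy loading is abrupt, crouch flexion baseline is elevated", {
  b <- synth_gait("bouncy", 2000, 101L, seed = 1L)
  s <- synth_gait("smooth", 2000, 101L, seed = 1L)
  expect_gt(max(abs(diff(b$Fz))), max(abs(diff(s$Fz))))
  cr <- synth_gait("crouch", 2000, 101L, seed = 1L)
  n <- synth_gait("normal", 2000, 101L, seed = 1L)
  expect_gt(min(cr$flexion), min(n$flexion) + 10)
  expect_error(synth_gait("normal", 2000, n_points = 10L), "n_points")
})

test_that("two-step load curves settle first, then replay the gait", {
  bc <- synth_gait("normal", 2000, 51L, seed = 2L, duration = 1)
  curves <- build_load_curves(bc, settle_duration = 0.1)
  expect_equal(curves$step_times, c(0.1, 1.1))
  expect_equal(eval_load_curve(curves$Fz, 0), 0)
  # settling: flexion and moment held at their initial values
  ts <- seq(0, 0.1, length.out = 11)
  expect_equal(eval_load_curve(curves$flexion, ts),
               rep(bc$flexion[1], 11))
  expect_equal(eval_load_curve(curves$My, ts), rep(bc$My[1], 11))
  # gait phase is the input shifted by the settle duration
  expect_equal(eval_load_curve(curves$Fz, bc$t + 0.1), bc$Fz,
               tolerance = 1e-12)
  expect_error(build_load_curves(bc, 0), "settle_duration")
})

test_that("the gait CSV schema round-trips", {
  bc <- synth_gait("crouch", 1500, 31L, seed = 5L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_gait_csv(bc, path)
  back <- read_gait_csv(path)
  expect_equal(back$Fz, bc$Fz, tolerance = 1e-12)
  expect_equal(back$flexion, bc$flexion, tolerance = 1e-12)
})

test_that("lab-frame vectors map to the model frame by the fixed permutation", {
  lab <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  mod <- lab_to_model_frame(lab)
  expect_equal(mod[1, ], c(0, 1, 0))    # forward -> anterior
  expect_equal(mod[2, ], c(-1, 0, 0))   # subject right -> -x
  expect_equal(mod[3, ], c(0, 0, 1))    # vertical unchanged
})
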