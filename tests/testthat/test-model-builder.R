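make_model <- function(resolution = 0.3, n_points = 21L, seed = 1L)
  build_synthetic_model(synthetic_geom_params(resolution = resolution),
                        synth_gait("normal", n_points = n_points,
                                   seed = seed))

test_that("the assembled model satisfies the structural contract", {
  m <- make_model()
  expect_length(m$contacts, 3L)
  expect_length(m$connectors, 3L)
  expect_length(m$ligaments, 2L)
  expect_length(m$steps, 2L)
  kinds <- vapply(m$contacts, `[[`, "", "kind")
  expect_equal(sort(kinds), c("rigid_tie", "rigid_tie", "sliding_elastic"))
  expect_equal(m$enabled_dofs,
               c("z_translation", "x_rotation", "y_rotation"))
  expect_setequal(m$constrained_parts, c("tibia", "fibula", "tibial_tray"))
  expect_equal(m$steps[[1]]$name, "settle")
  axes <- vapply(m$connectors, function(cx) which(cx$axis == 1), 0L)
  expect_equal(unname(axes), c(1L, 3L, 2L))   # flexion x, distraction z, vv y
})

test_that("assembly errors name the missing ingredient", {
  geo <- make_synthetic_tkr(synthetic_geom_params(resolution = 0.3))
  mats <- default_materials()
  bundles <- make_default_bundles()
  curves <- build_load_curves(synth_gait("normal", n_points = 21L))
  parts <- list(
    femur = body_part("femur", geo$femur_stub, mats$femur),
    tibia = body_part("tibia", geo$tibia_stub, mats$tibia),
    fibula = body_part("fibula", geo$fibula_stub, mats$fibula),
    tibial_tray = body_part("tibial_tray", geo$tibial_tray,
                            mats$tibial_tray),
    femoral_component = body_part(
      "femoral_component", tetrahedralize(geo$femoral_component),
      mats$femoral_component),
    tibial_insert = body_part(
      "tibial_insert", tetrahedralize(geo$tibial_insert),
      mats$tibial_insert))

  expect_error(assemble_model(parts[-4L], bundles, curves), "tibial_tray")
  no_my <- curves; no_my$My <- NULL
  expect_error(assemble_model(parts, bundles, no_my), "My")
  # deformable part demands a volumetric mesh
  expect_error(body_part("tibial_insert", geo$tibial_insert,
                         mats$tibial_insert), "tet_mesh")
})

test_that("FEB write -> summarize is the identity on all counts", {
  m <- make_model()
  path <- withr::local_tempfile(fileext = ".feb")
  write_feb(m, path)
  d <- summarize_feb(path)
  mc <- tkrfem:::model_counts(m)
  for (nm in names(mc))
    expect_equal(d[[nm]], mc[[nm]], label = nm)
  expect_equal(d$n_steps, 2L)
  expect_equal(d$spec_version, "3.0")
})

test_that("material constants serialize exactly", {
  m <- make_model()
  path <- withr::local_tempfile(fileext = ".feb")
  write_feb(m, path)
  x <- xml2::read_xml(path)
  up <- xml2::xml_find_first(x, '//material[@name="UHMWPE"]')
  expect_equal(xml2::xml_text(xml2::xml_find_first(up, "E")), "1200")
  expect_equal(xml2::xml_text(xml2::xml_find_first(up, "v")), "0.46")
  co <- xml2::xml_find_first(x, '//material[@name="CoCrMo"]')
  expect_equal(xml2::xml_text(xml2::xml_find_first(co, "E")), "210000")
  expect_equal(xml2::xml_text(xml2::xml_find_first(co, "v")), "0.3")
  expect_equal(xml2::xml_attr(up, "type"), "neo-Hookean")
  expect_equal(xml2::xml_attr(
    xml2::xml_find_first(x, '//material[@name="rigid_femur"]'), "type"),
    "rigid body")
})

test_that("writing the same model twice is byte-identical", {
  m <- make_model()
  p1 <- withr::local_tempfile(fileext = ".feb")
  p2 <- withr::local_tempfile(fileext = ".feb")
  write_feb(m, p1)
  write_feb(m, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
})

test_that("round-trip fidelity holds across randomized configurations", {
  for (seed in 1:3) {
    set.seed(seed)
    m <- build_synthetic_model(
      synthetic_geom_params(resolution = runif(1, 0.25, 0.4),
                            condyle_spacing = runif(1, 40, 50)),
      synth_gait(sample(c("normal", "bouncy", "smooth"), 1),
                 n_points = sample(21:41, 1), seed = seed))
    path <- withr::local_tempfile(fileext = ".feb")
    write_feb(m, path)
    d <- summarize_feb(path)
    mc <- tkrfem:::model_counts(m)
    for (nm in names(mc))
      expect_equal(d[[nm]], mc[[nm]],
                   label = sprintf("seed %d %s", seed, nm))
  }
})

test_that("malformed and empty files are handled", {
  path <- withr::local_tempfile(fileext = ".feb")
  m <- make_model()
  write_feb(m, path)
  txt <- readLines(path)
  writeLines(txt[1:(length(txt) %/% 2)], path)      # truncate
  expect_error(summarize_feb(path), "parse|XML")

  empty <- withr::local_tempfile(fileext = ".feb")
  writeLines('<febio_spec version="3.0"></febio_spec>', empty)
  d <- summarize_feb(empty)
  expect_equal(d$n_nodes, 0L)
  expect_equal(d$n_contacts, 0L)

  expect_error(write_feb(m, path, spec_version = "9.9"), "spec version")
})
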