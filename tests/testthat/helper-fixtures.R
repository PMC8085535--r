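# shared fixtures, built in code

unit_cube <- function() tkrfem:::box_surface(c(0, 0, 0), c(1, 1, 1),
                                             name = "cube")

test_sphere <- function(center = c(0, 0, 0), radius = 1, n = 16L)
  tkrfem:::uv_sphere(center, radius, n_theta = 2L * n, n_phi = n)

# flat-topped block for contact oracles (top at z = height)
flat_block <- function(half = 6, height = 8, nx = 24L)
  tkrfem:::heightfield_block(c(-half, half), c(-half, half), 0,
                             function(x, y) rep(height, length(x)),
                             nx = nx, ny = nx, name = "flat_block")

# random convex body: ellipsoid = linearly stretched sphere
random_convex <- function(seed) {
  set.seed(seed)
  s <- test_sphere(radius = 1, n = 12L)
  A <- diag(runif(3, 0.5, 2))
  ang <- runif(1, 0, 180)
  R <- tkrfem:::rotation_matrix(c(runif(2), 1 + runif(1)), ang)
  s$vertices <- s$vertices %*% t(R %*% A)
  s
}

random_bundle <- function(seed) {
  set.seed(seed)
  ligament_bundle(sprintf("lig%d", seed),
                  origin = runif(3, -30, 30),
                  insertion = runif(3, -30, 30) + c(0, 0, -50),
                  k = runif(1, 1000, 10000),
                  eps_r = runif(1, -0.08, 0.08),
                  eps_l = runif(1, 0.01, 0.06))
}

# small contact setup shared by solver tests
small_knee <- function(resolution = 0.5) {
  gp <- synthetic_geom_params(resolution = resolution)
  geo <- make_synthetic_tkr(gp)
  fnd <- foundation_model(geo$tibial_insert)
  bundles <- make_default_bundles(synthetic_landmarks(gp))
  jc <- c(0, 0, tkrfem:::condyle_center_z(gp))
  list(gp = gp, geo = geo, fnd = fnd, bundles = bundles, jc = jc,
       model = contact_model(geo$femoral_component, fnd, bundles,
                             joint_center = jc))
}

extdata <- function(file)
  system.file("extdata", file, package = "tkrfem", mustWork = TRUE)
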