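test_that("assembly uses harmonic-mean face conductances and yields a
          symmetric weakly diagonally dominant system", {
  g <- voxel_grid(c(2L, 1L, 1L), c(1e-4, 2e-4, 3e-4))
  lab <- label_map(array(LABEL_TUMOR, dim = c(2, 1, 1)), cut_ends = "x-")
  kn <- array(0, dim = c(2, 1, 1))
  src <- source_field(kn, lab, tissue_params())
  Kv <- 1.9e-12
  K <- array(c(Kv, 3 * Kv), dim = c(2, 1, 1))
  sys <- assemble_pressure_system(K, src, classify_boundary(g, lab), g)
  area_d <- (2e-4 * 3e-4) / 1e-4
  expect_equal(sys$A[1, 2], -area_d * 1.5 * Kv, tolerance = 1e-12)

  rp <- random_phantom(31L)
  maps <- rp$maps
  par <- tissue_params()
  kn <- normalize_ktrans(maps$ktrans, maps$labels)$ktrans_norm
  Kh <- conductivity_map(maps$phi, maps$labels, par)
  srch <- source_field(kn, maps$labels, par,
                       protocol = infusion_protocol(rp$site), grid = maps$grid)
  sysh <- assemble_pressure_system(Kh, srch,
                                   classify_boundary(maps$grid, maps$labels),
                                   maps$grid)
  M <- as(sysh$A, "generalMatrix")
  expect_true(Matrix::isSymmetric(sysh$A))
  slack <- Matrix::diag(M) - (Matrix::rowSums(abs(M)) - abs(Matrix::diag(M)))
  expect_true(all(slack > -1e-25))
})

test_that("a 1-D constant-rate infusion column reproduces the exact discrete
          Darcy solution and velocity", {
  n <- 20L; h <- 1e-4
  g <- voxel_grid(c(n, 1L, 1L), rep(h, 3))
  lab <- label_map(array(LABEL_TUMOR, dim = c(n, 1, 1)), cut_ends = "x-")
  kn <- array(0, dim = c(n, 1, 1))
  prot <- infusion_protocol(c(n, 1L, 1L), Q_uL_min = 0.1)
  src <- source_field(kn, lab, tissue_params(), protocol = prot, grid = g)
  Kv <- 1.9e-12
  K <- array(Kv, dim = c(n, 1, 1))
  bcs <- classify_boundary(g, lab)
  sys <- assemble_pressure_system(K, src, bcs, g)
  sol <- solve_pressure(sys)
  A <- h * h
  p_exact <- prot$Q * h * (seq_len(n) - 0.5) / (Kv * A)
  expect_rel_equal(as.numeric(sol$pressure), p_exact, 1e-10)

  phi <- array(0.4, dim = c(n, 1, 1))
  vel <- compute_velocity(sol$pressure, K, phi, g, bcs, lab)
  # Darcy's law: |v| = K dp/dx = Q/A away from the source cell
  expect_rel_equal(abs(vel$qx[2:(n - 1), 1, 1]), rep(prot$Q / A, n - 2L), 1e-10)
  expect_equal(vel$boundary_outflux, prot$Q, tolerance = 1e-8)
  # interstitial velocity is the pore velocity
  expect_rel_equal(vel$speed_ifv[2:(n - 1), 1, 1],
                   rep(prot$Q / A / 0.4, n - 2L), 1e-10)

  # uniform pressure means zero velocity
  v0 <- compute_velocity(array(5, dim = c(n, 1, 1)), K, phi, g,
                         bcs[bcs$bc == "NOFLUX", ], lab)
  expect_equal(max(abs(v0$speed)), 0)
})

test_that("degenerate systems behave: all-Dirichlet no-source gives p = 0 and
          a sourceless sealed box is singular", {
  shape <- c(4L, 4L, 3L)
  g <- voxel_grid(shape, rep(1e-4, 3))
  lab_all <- label_map(array(LABEL_TUMOR, dim = shape),
                       cut_ends = c("x-", "x+", "y-", "y+", "z-", "z+"))
  kn0 <- array(0, dim = shape)
  src0 <- source_field(kn0, lab_all, tissue_params())
  K <- array(1e-12, dim = shape)
  sol <- solve_pressure(assemble_pressure_system(
    K, src0, classify_boundary(g, lab_all), g))
  expect_equal(max(abs(sol$pressure)), 0)

  sealed <- label_map(array(LABEL_TUMOR, dim = shape), cut_ends = character(0))
  expect_error(
    assemble_pressure_system(K, src0, classify_boundary(g, sealed), g),
    class = "cedsim_singular_error")
})

test_that("a sealed homogeneous tumor equilibrates at the Starling effective
          pressure", {
  shape <- c(6L, 6L, 6L)
  g <- voxel_grid(shape, rep(1e-3, 3))
  lab <- label_map(array(LABEL_TUMOR, dim = shape), cut_ends = character(0))
  par <- tissue_params()
  src <- source_field(array(1, dim = shape), lab, par)
  K <- array(par$K0_tumor, dim = shape)
  sol <- solve_pressure(assemble_pressure_system(
    K, src, classify_boundary(g, lab), g))
  expect_rel_equal(as.numeric(sol$pressure),
                   rep(effective_pressure(par, "tumor"), prod(shape)), 1e-10)
})

test_that("the full flow solve conserves mass, is deterministic, and responds
          monotonically to the infusion rate", {
  rp <- random_phantom(17L)
  par <- tissue_params()
  p_site <- vapply(c(0.3, 1, 3), function(q) {
    fl <- solve_flow(rp$maps, par,
                     protocol = infusion_protocol(rp$site, Q_uL_min = q))
    expect_lt(fl$mass_balance_rel, 1e-3)
    expect_lt(fl$residual_norm, 1e-8)
    fl$pressure[rp$site[1], rp$site[2], rp$site[3]]
  }, numeric(1))
  expect_true(all(diff(p_site) > 0))

  f1 <- solve_flow(rp$maps, par, protocol = infusion_protocol(rp$site))
  f2 <- solve_flow(rp$maps, par, protocol = infusion_protocol(rp$site))
  expect_identical(f1$pressure, f2$pressure)
})

test_that("skin impermeability keeps interface velocities far below the
          interior peak on the baseline phantom", {
  maps <- make_phantom(phantom_spec(), default_grid(2L))
  site <- site_tumor_centroid(maps$labels)
  flow <- solve_flow(maps, tissue_params(),
                     protocol = infusion_protocol(site))
  sk <- skin_interface_speed(flow, maps$labels)
  expect_lt(sk$ratio, 0.01)
})
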