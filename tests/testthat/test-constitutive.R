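test_that("conductivity matches K0 at the average porosity and scales as
          phi^gamma per tissue", {
  par <- tissue_params()
  shape <- c(4L, 1L, 1L)
  lab <- label_map(array(c(LABEL_TUMOR, LABEL_TUMOR, LABEL_HOST,
                           LABEL_EXTERIOR), dim = shape))
  phi <- array(c(0.40, 0.20, 0.20, NA), dim = shape)

  K <- conductivity_map(phi, lab, par, gamma = 5)
  expect_equal(K[1, 1, 1], par$K0_tumor)                    # phi = phi0
  expect_equal(K[2, 1, 1], par$K0_tumor / 32)               # (0.5)^5
  expect_equal(K[3, 1, 1], par$K0_host)                     # host matching
  expect_equal(K[4, 1, 1], par$K0_exterior)                 # constant exterior

  # gamma = 0 switches heterogeneity off entirely
  K0 <- conductivity_map(array(c(0.1, 0.7, 0.5, NA), dim = shape), lab, par,
                         gamma = 0)
  expect_equal(K0[1, 1, 1], par$K0_tumor)
  expect_equal(K0[3, 1, 1], par$K0_host)

  # monotone increasing in phi for gamma > 0; continuous in gamma
  phis <- seq(0.05, 0.95, by = 0.05)
  labs1 <- label_map(array(LABEL_TUMOR, dim = c(length(phis), 1, 1)))
  Km <- conductivity_map(array(phis, dim = c(length(phis), 1, 1)), labs1, par,
                         gamma = 3)
  expect_true(all(diff(as.numeric(Km)) > 0))
  Ka <- conductivity_map(array(0.3, dim = c(1, 1, 1)),
                         label_map(array(LABEL_TUMOR, dim = c(1, 1, 1))), par,
                         gamma = 3 + 1e-9)
  Kb <- conductivity_map(array(0.3, dim = c(1, 1, 1)),
                         label_map(array(LABEL_TUMOR, dim = c(1, 1, 1))), par,
                         gamma = 3)
  expect_equal(Ka[1, 1, 1], Kb[1, 1, 1], tolerance = 1e-6)

  expect_error(conductivity_map(phi, lab, tissue_params(phi0_tumor = 1e-300),
                                gamma = 3), NA)  # tiny but positive phi0 ok
  expect_error(conductivity_map(array(c(0, 0.2, 0.2, NA), dim = shape), lab,
                                par), "porosity")
})

test_that("effective diffusivity follows D_free * phi^n with zero exterior", {
  par <- tissue_params()
  shape <- c(3L, 1L, 1L)
  lab <- label_map(array(c(LABEL_TUMOR, LABEL_HOST, LABEL_EXTERIOR),
                         dim = shape))
  D <- effective_diffusivity(array(c(1, 0.5, NA), dim = shape), lab, par)
  expect_equal(D[1, 1, 1], 5.8e-11)
  expect_equal(D[2, 1, 1], 5.8e-11 / 2)
  expect_equal(D[3, 1, 1], 0)
  par2 <- tissue_params(n_diff = 2)
  D2 <- effective_diffusivity(array(c(0.3, 0.3, NA), dim = shape), lab, par2)
  expect_equal(D2[1, 1, 1], 0.09 * 5.8e-11)
})

test_that("Starling source is affine and stabilising, with host-only
          lymphatics", {
  par <- tissue_params()
  shape <- c(3L, 1L, 1L)
  lab <- label_map(array(c(LABEL_TUMOR, LABEL_HOST, LABEL_EXTERIOR),
                         dim = shape))
  kn <- array(c(1, 1, 0), dim = shape)

  # effective-pressure root: source vanishes at p = p_eff
  p_eq <- array(c(effective_pressure(par, "tumor"),
                  effective_pressure(par, "host"), 0), dim = shape)
  s_eq <- starling_source(p_eq, kn, lab, par)
  expect_equal(max(abs(s_eq)), 0, tolerance = 1e-18)

  # tumor voxel at p = 0: Lp (S/V) (2300 - 0.82 (2670 - 3230))
  s0 <- starling_source(array(0, dim = shape), kn, lab, par)
  expect_equal(s0[1, 1, 1], 2e-11 * 20000 * 2759.2, tolerance = 1e-12)
  expect_equal(s0[3, 1, 1], 0)                      # exterior
  expect_equal(starling_source(array(0, dim = shape),
                               array(0, dim = shape), lab, par)[1, 1, 1],
               0)                                   # avascular voxel

  # monotone decreasing in p
  s1 <- starling_source(array(100, dim = shape), kn, lab, par)
  expect_true(all(s1[1:2, 1, 1] < s0[1:2, 1, 1]))

  src <- source_field(kn, lab, par)
  expect_equal(src$lymph[1, 1, 1], 0)               # no tumor lymphatics
  expect_equal(src$lymph[2, 1, 1], par$lymph_coeff)
  expect_equal(src$lymph[3, 1, 1], 0)
  expect_true(all(src$a[3, 1, 1] == 0 & src$b[3, 1, 1] == 0))
  # affine coefficients agree with the direct evaluation
  p <- array(c(500, 700, 0), dim = shape)
  expect_equal(src$a - src$b * p,
               starling_source(p, kn, lab, par) - src$lymph * (p - par$p_L),
               tolerance = 1e-15)
})

test_that("parameter registry validates Table values and rejects nonsense", {
  par <- tissue_params()
  expect_equal(effective_pressure(par, "tumor"), 2759.2)
  expect_equal(effective_pressure(par, "host"),
               2300 - 0.91 * (2670 - 1330))
  expect_error(tissue_params(sigma_tumor = 1.2), "reflection")
  expect_error(tissue_params(phi0_host = 0), "porosities")
  expect_error(tissue_params(K0_tumor = -1), "> 0")
  expect_error(tissue_params(bogus = 1), "unknown parameter")
  # unit conversion for the infusion rate: 0.3 uL/min = 5e-12 m^3/s
  prot <- infusion_protocol(c(1, 1, 1), Q_uL_min = 0.3)
  expect_equal(prot$Q, 5e-12)
})
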