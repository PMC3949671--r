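test_that("distribution volume applies the 15% threshold by definition", {
  shape <- c(3L, 1L, 1L)
  g <- voxel_grid(shape, rep(1e-3, 3))
  lmap <- label_map(array(LABEL_TUMOR, dim = shape))
  dv <- distribution_volume(array(c(1, 0.2, 0.1), dim = shape), lmap, g)
  expect_equal(dv$threshold, 0.15)
  expect_equal(dv$Vd_whole, 2 * g$voxel_volume)
  expect_equal(dv$Vd_tumor, 2 * g$voxel_volume)

  # uniform tumor concentration -> full coverage
  dv1 <- distribution_volume(array(1, dim = shape), lmap, g)
  expect_equal(dv1$coverage, 1)

  # all-zero field is a zero Vd, not an error
  dv0 <- distribution_volume(array(0, dim = shape), lmap, g)
  expect_equal(dv0$Vd_whole, 0)
})

test_that("distribution volume agrees with a brute-force recount and is
          monotone in the threshold", {
  rp <- random_phantom(12L)
  g <- rp$maps$grid
  lmap <- rp$maps$labels
  cc <- withr::with_seed(2L, array(stats::runif(prod(g$shape)), dim = g$shape))
  tis <- lmap$labels != LABEL_EXTERIOR
  for (f in c(0.1, 0.15, 0.5)) {
    dv <- distribution_volume(cc, lmap, g, threshold_fraction = f)
    brute <- 0L
    thr <- f * max(cc[tis])
    for (i in seq_len(g$shape[1])) for (j in seq_len(g$shape[2]))
      for (k in seq_len(g$shape[3])) {
        if (lmap$labels[i, j, k] != LABEL_EXTERIOR && cc[i, j, k] > thr)
          brute <- brute + 1L
      }
    expect_equal(dv$Vd_whole, brute * g$voxel_volume)
  }
  fr <- seq(0.05, 0.95, by = 0.1)
  vds <- vapply(fr, function(f)
    distribution_volume(cc, lmap, g, f)$Vd_whole, numeric(1))
  expect_true(all(diff(vds) <= 0))
})

test_that("Vd-Vi fits recover generating parameters (inverse crime) and
          rank models correctly on saturating data", {
  vi <- seq(0.5, 16, length.out = 8)
  line <- 3 + 2 * vi
  lf <- fit_vd_vi(vi, line, "linear")
  expect_equal(lf$slope, 2, tolerance = 1e-12)
  expect_equal(lf$intercept, 3, tolerance = 1e-12)
  expect_equal(lf$r_squared, 1)

  sat <- 10 * (1 - exp(-vi / 2))
  ef <- fit_vd_vi(vi, sat, "exponential")
  expect_lt(abs(ef$Vmax - 10), 1e-6)
  expect_lt(abs(ef$tau - 2), 1e-6)

  expect_gt(ef$r_squared, fit_vd_vi(vi, sat, "linear")$r_squared)
  expect_error(fit_vd_vi(rep(2, 5), 1:5), class = "cedsim_fit_error")
})

test_that("centre-of-mass offset is zero for a symmetric blob and positive
          for a lopsided one", {
  shape <- c(9L, 9L, 3L)
  g <- voxel_grid(shape, rep(1e-3, 3))
  lmap <- label_map(array(LABEL_TUMOR, dim = shape))
  cc <- array(0, dim = shape)
  cc[4:6, 4:6, 2] <- 1
  off <- tracer_com_offset(cc, lmap, g, c(5L, 5L, 2L))
  expect_lt(off$offset_voxels, 1e-10)
  cc[7:9, 5, 2] <- 1
  off2 <- tracer_com_offset(cc, lmap, g, c(5L, 5L, 2L))
  expect_gt(off2$offset_voxels, 0.3)
})

test_that("catheter-site presets land on sensible tumor voxels", {
  maps <- make_phantom(phantom_spec(), default_grid(4L))
  lab <- maps$labels$labels
  ctr <- site_tumor_centroid(maps$labels)
  inter <- site_interface(maps$labels)
  ant <- site_anterior(maps$labels)
  for (s in list(ctr, inter, ant)) {
    expect_equal(lab[s[1], s[2], s[3]], LABEL_TUMOR)
  }
  expect_gt(ant[1], ctr[1])               # anterior lies further along x
  # interface preset touches host tissue
  nb <- rbind(inter + c(1, 0, 0), inter - c(1, 0, 0),
              inter + c(0, 1, 0), inter - c(0, 1, 0),
              inter + c(0, 0, 1), inter - c(0, 0, 1))
  nb_lab <- apply(nb, 1, function(s) {
    if (any(s < 1) || any(s > dim(lab))) NA_integer_
    else lab[s[1], s[2], s[3]]
  })
  expect_true(any(nb_lab == LABEL_HOST, na.rm = TRUE))
})

test_that("a single-cell study equals a direct run and failures are reported
          without aborting the study", {
  rp <- random_phantom(44L)
  par <- tissue_params()
  sites <- list(center = rp$site)
  st <- run_parameter_study(rp$maps, par, flow_rates = 0.3, sites = sites,
                            gammas = 3, duration = 600,
                            output_times = c(300, 600), dt = 30)
  direct <- run_ced_case(rp$maps, par,
                         infusion_protocol(rp$site, 0.3, 600,
                                           c(300, 600)),
                         gamma = 3, dt = 30)
  expect_equal(st$results$Vd_whole, direct$table$Vd_whole)
  expect_equal(st$results$coverage, direct$table$coverage)

  bad_sites <- list(center = rp$site, outside = c(1L, 1L, 1L))
  st2 <- run_parameter_study(rp$maps, par, flow_rates = 0.3,
                             sites = bad_sites, gammas = 3, duration = 600,
                             output_times = 600, dt = 30)
  ok <- vapply(st2$runs, function(r) isTRUE(r$ok), logical(1))
  expect_equal(sum(!ok), 1L)
  expect_match(st2$runs[[which(!ok)]]$error, "EXTERIOR")
})
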