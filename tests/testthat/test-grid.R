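test_that("voxel grid invariants and default imaging geometry hold", {
  g <- voxel_grid(c(4, 3, 2), c(1e-3, 2e-3, 0.5e-3))
  expect_equal(g$voxel_volume, prod(g$spacing))
  expect_equal(g$extent, c(4e-3, 6e-3, 1e-3))
  expect_error(voxel_grid(c(4, 3, 2), c(1e-3, 0, 1e-3)), "positive")

  d <- default_grid()
  expect_equal(d$shape, c(192L, 96L, 9L))
  expect_equal(d$spacing, c(0.104e-3, 0.104e-3, 1e-3))
  expect_equal(d$extent, c(19.968e-3, 9.984e-3, 9e-3), tolerance = 1e-12)
})

test_that("boundary classification is exhaustive, exclusive, and puts
          Dirichlet only on tissue cut-end faces", {
  shape <- c(6L, 5L, 4L)
  lab <- array(LABEL_HOST, dim = shape)
  lab[, , 1] <- LABEL_EXTERIOR           # exterior slab at z-
  lmap <- label_map(lab, cut_ends = c("x-", "x+", "z-"))
  g <- voxel_grid(shape, rep(1e-3, 3))
  bc <- classify_boundary(g, lmap)

  n_outer <- 2 * (shape[2] * shape[3] + shape[1] * shape[3] +
                  shape[1] * shape[2])
  expect_equal(nrow(bc), n_outer)
  expect_true(all(bc$bc %in% c("DIRICHLET_P0", "NOFLUX")))
  key <- paste(bc$side, bc$ix, bc$iy, bc$iz)
  expect_equal(anyDuplicated(key), 0L)

  # tissue cross-sections at the x cut ends -> Dirichlet, except the
  # exterior z = 1 layer
  xm <- bc[bc$side == "x-", ]
  expect_true(all(xm$bc[xm$iz > 1] == "DIRICHLET_P0"))
  expect_true(all(xm$bc[xm$iz == 1] == "NOFLUX"))
  # z- is flagged as a cut end but is all exterior -> no Dirichlet there
  expect_true(all(bc$bc[bc$side == "z-"] == "NOFLUX"))
  # unflagged sides stay walls
  expect_true(all(bc$bc[bc$side %in% c("y-", "y+", "z+")] == "NOFLUX"))

  # single-voxel domain: Dirichlet iff the face is a flagged cut end
  g1 <- voxel_grid(c(1, 1, 1), rep(1e-3, 3))
  l1 <- label_map(array(LABEL_TUMOR, dim = c(1, 1, 1)),
                  cut_ends = c("x-", "x+"))
  bc1 <- classify_boundary(g1, l1)
  expect_equal(sum(bc1$bc == "DIRICHLET_P0"), 2L)
  l0 <- label_map(array(LABEL_TUMOR, dim = c(1, 1, 1)), cut_ends = character(0))
  expect_equal(sum(classify_boundary(g1, l0)$bc == "DIRICHLET_P0"), 0L)
})

test_that("maps survive a save/load round trip bit-exactly", {
  maps <- tiny_phantom(seed = 3L)
  pre <- file.path(tempdir(), "rt")
  save_maps(maps, pre)
  back <- load_maps(pre)
  expect_identical(back$labels$labels, maps$labels$labels)
  expect_identical(back$labels$cut_ends, maps$labels$cut_ends)
  expect_identical(back$ktrans, maps$ktrans)
  expect_identical(back$phi, maps$phi)
  expect_identical(back$grid$spacing, maps$grid$spacing)
})

test_that("loading mismatched volumes fails naming the offending axis", {
  a <- tiny_phantom(seed = 3L, shape = c(24L, 16L, 5L))
  b <- tiny_phantom(seed = 3L, shape = c(24L, 16L, 4L))
  pa <- file.path(tempdir(), "mmA"); pb <- file.path(tempdir(), "mmB")
  save_maps(a, pa); save_maps(b, pb)
  file.copy(paste0(pb, "_phi.nii.gz"), paste0(pa, "_phi.nii.gz"),
            overwrite = TRUE)
  err <- tryCatch(load_maps(pa), error = function(e) e)
  expect_s3_class(err, "cedsim_shape_error")
  expect_match(conditionMessage(err), "phi")
  expect_match(conditionMessage(err), "axis z")
})

test_that("out-of-range porosity is clipped with a counted warning", {
  maps <- tiny_phantom(seed = 3L)
  bad <- which(maps$labels$labels == LABEL_HOST)[1:3]
  maps$phi[bad] <- 1.2
  pre <- file.path(tempdir(), "oob")
  save_maps(maps, pre)
  expect_warning(back <- load_maps(pre), "3 voxels")
  expect_true(all(back$phi[bad] <= 0.99))
})

test_that("ktrans declared in 1/min is converted to SI at load", {
  maps <- tiny_phantom(seed = 3L)
  pre <- file.path(tempdir(), "units")
  save_maps(maps, pre)
  meta <- jsonlite::read_json(paste0(pre, "_meta.json"), simplifyVector = TRUE)
  meta$ktrans_units <- "1/min"
  jsonlite::write_json(meta, paste0(pre, "_meta.json"), auto_unbox = TRUE,
                       digits = NA)
  back <- load_maps(pre)
  expect_equal(back$ktrans, maps$ktrans / 60, tolerance = 1e-12)
})

test_that("a YAML run configuration round-trips into typed objects", {
  cfg_file <- file.path(tempdir(), "run.yaml")
  writeLines(c(
    "grid:",
    "  scale: 4",
    "tissue:",
    "  gamma: 5",
    "  K0_tumor: 2.0e-12",
    "phantom:",
    "  seed: 7",
    "  heterogeneity_cv: 0.2",
    "infusion:",
    "  site: [24, 12, 5]",
    "  Q_uL_min: 1.0",
    "  duration: 1800",
    "  output_times: [900, 1800]"
  ), cfg_file)
  cfg <- read_config(cfg_file)
  expect_equal(cfg$grid$shape, c(48L, 24L, 9L))
  expect_equal(cfg$params$gamma, 5)
  expect_equal(cfg$params$K0_tumor, 2.0e-12)
  expect_equal(cfg$params$Lp_tumor, 2e-11)       # untouched default
  expect_equal(cfg$phantom$seed, 7L)
  expect_equal(cfg$protocol$Q, 1e-9 / 60)
  expect_equal(cfg$protocol$output_times, c(900, 1800))

  prov <- file.path(tempdir(), "prov.json")
  write_provenance(prov, cfg_file, seed = 7L)
  rec <- jsonlite::read_json(prov)
  expect_equal(rec$package, "cedsim")
  expect_equal(rec$seed, 7L)
  expect_false(is.null(rec$config_md5))
})
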