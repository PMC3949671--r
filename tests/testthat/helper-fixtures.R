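# Shared fixtures: everything is generated in code at test time.

# small leg-like phantom on a coarse grid (fast flow + transport)
tiny_phantom <- function(seed = 7L, cv = 0.3, shape = c(24L, 16L, 5L),
                         radii = NULL) {
  grid <- voxel_grid(shape, c(0.8e-3, 0.6e-3, 1e-3))
  if (is.null(radii)) {
    radii <- pmin(c(4e-3, 2.5e-3, 1.5e-3),
                  0.3 * grid$extent)
  }
  spec <- phantom_spec(tumor_radii = radii,
                       heterogeneity_cv = cv, correlation_length = 1.2e-3,
                       seed = seed)
  make_phantom(spec, grid)
}

# tumor voxels adjacent to a non-tumor voxel
tumor_shell_mask <- function(lab) {
  shape <- dim(lab)
  sh <- array(FALSE, dim = shape)
  tum <- lab == LABEL_TUMOR
  idx <- which(tum, arr.ind = TRUE)
  for (ax in 1:3) {
    for (s in c(-1L, 1L)) {
      nb <- idx; nb[, ax] <- nb[, ax] + s
      ok <- nb[, ax] >= 1L & nb[, ax] <= shape[ax]
      lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * shape[1] +
        (nb[ok, 3] - 1L) * shape[1] * shape[2]
      hit <- lab[lin] != LABEL_TUMOR
      sh[idx[ok, , drop = FALSE][hit, , drop = FALSE]] <- TRUE
    }
  }
  sh
}

# hand-built random heterogeneous phantom: tumor core, host shell,
# exterior margin; used for property-style suites
random_phantom <- function(seed, shape = c(12L, 10L, 6L)) {
  withr::with_seed(seed, {
    grid <- voxel_grid(shape, c(3e-4, 3e-4, 5e-4))
    lab <- array(LABEL_EXTERIOR, dim = shape)
    lab[2:(shape[1] - 1L), 2:(shape[2] - 1L), ] <- LABEL_HOST
    tx <- 4:(shape[1] - 3L); ty <- 4:(shape[2] - 3L); tz <- 2:(shape[3] - 1L)
    lab[tx, ty, tz] <- LABEL_TUMOR
    lmap <- label_map(lab, cut_ends = c("x-", "x+"))
    tis <- lab != LABEL_EXTERIOR
    ktrans <- array(0, dim = shape)
    ktrans[tis] <- stats::rlnorm(sum(tis), log(0.05 / 60), 0.6)
    phi <- array(NA_real_, dim = shape)
    phi[tis] <- stats::runif(sum(tis), 0.1, 0.6)
    list(maps = ced_maps(grid, lmap, ktrans, phi),
         site = c(tx[length(tx) %/% 2 + 1L], ty[length(ty) %/% 2 + 1L],
                  tz[length(tz) %/% 2 + 1L]))
  })
}

# 1-D column transport setup with a prescribed uniform Darcy flux and/or
# diffusivity; site (held c = 1) at the first voxel
column_setup <- function(n = 300L, h = 1e-3, phi0 = 0.5, q = 0, Deff = 0) {
  grid <- voxel_grid(c(n, 1L, 1L), rep(h, 3))
  area <- h * h
  fx <- array(0, dim = c(n + 1L, 1L, 1L))
  fx[2:n, 1, 1] <- q * area
  flow <- list(fx = fx, fy = array(0, dim = c(n, 2L, 1L)),
               fz = array(0, dim = c(n, 1L, 2L)))
  list(grid = grid, flow = flow,
       phi = array(phi0, dim = grid$shape),
       Deff = array(Deff, dim = grid$shape))
}

expect_rel_equal <- function(x, y, tol) {
  testthat::expect_lt(max(abs(x - y) / pmax(abs(y), .Machine$double.eps)), tol)
}
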