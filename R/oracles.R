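# Closed-form verification oracles for the pressure solver.

# exact axis-aligned crossing distance from a point to the sphere |x| = R
# (second-order embedded boundary; linear level-set interpolation is only
# first-order on curved boundaries)
.sphere_crossing <- function(R) {
  function(px, py, pz, ax, sgn) {
    a <- switch(ax, px, py, pz)
    rho2 <- px^2 + py^2 + pz^2 - a^2
    sqrt(pmax(R^2 - rho2, 0)) - sgn * a
  }
}

#' Screened-sphere pressure profile (closed form)
#'
#' Steady IFP in a homogeneous spherical tumor of radius `R` with uniform
#' Starling filtration (no lymphatics) and `p = 0` at the rim:
#' \deqn{p(r) = p_{eff} [1 - (R/r) \sinh(\alpha r/R)/\sinh\alpha],\quad
#'       \alpha = R\sqrt{L_p (S/V) / K}.}
#' The profile is flat near the core (elevated, near-uniform tumor IFP) and
#' drops steeply at the periphery.
#'
#' @param params a [tissue_params]; tumor values are used.
#' @param R sphere radius \[m\].
#' @param r radii at which to evaluate \[m\] (0 allowed).
#' @param gamma unused placeholder for interface symmetry.
#' @return numeric vector of pressures \[Pa\].
#' @export
screened_sphere_profile <- function(params, R, r, gamma = NULL) {
  t <- tissue_of(params, "tumor")
  alpha <- R * sqrt(t$Lp * t$SV / t$K0)
  p_eff <- effective_pressure(params, "tumor")
  x <- alpha * r / R
  ratio <- ifelse(r < R * 1e-8, alpha, (R / r) * sinh(x))
  p_eff * (1 - ratio / sinh(alpha))
}

#' Finite-volume vs closed-form screened sphere benchmark
#'
#' Embeds a homogeneous tumor sphere in an `n^3` cube (embedded Dirichlet
#' rim via the level set `r - R`), solves the FV pressure system with the
#' uniform Starling source, and reports the relative L2 error against
#' [screened_sphere_profile()] over all solved cells.
#'
#' @param n cells per axis.
#' @param params a [tissue_params].
#' @param R sphere radius \[m\].
#' @param margin box half-width as a multiple of `R`.
#' @return list: `rel_l2_error`, `n`, `h` (spacing), `pressure`, `analytic`,
#'   `mask`, `grid`.
#' @export
sphere_benchmark <- function(n = 64, params = tissue_params(), R = 4e-3,
                             margin = 1.05) {
  h <- 2 * R * margin / n
  grid <- voxel_grid(c(n, n, n), rep(h, 3), origin = rep(-R * margin + h / 2, 3))
  cx <- axis_coords(grid, 1); cy <- axis_coords(grid, 2); cz <- axis_coords(grid, 3)
  r <- sqrt(outer(outer(cx^2, cy^2, `+`), cz^2, `+`))
  mask <- r < R
  levelset <- r - R
  lmap <- label_map(array(LABEL_TUMOR, dim = grid$shape), cut_ends = character(0))
  kn <- array(1, dim = grid$shape)
  src <- source_field(kn, lmap, params)        # tumor: Starling only, no lymph
  K <- array(tissue_of(params, "tumor")$K0, dim = grid$shape)
  sys <- assemble_pressure_system(K, src, bcs = NULL, grid = grid,
                                  mask = mask, levelset = levelset,
                                  crossing_fun = .sphere_crossing(R))
  sol <- solve_pressure(sys)
  pa <- array(NA_real_, dim = grid$shape)
  pa[mask] <- screened_sphere_profile(params, R, r[mask])
  err <- sqrt(sum((sol$pressure[mask] - pa[mask])^2) / sum(pa[mask]^2))
  list(rel_l2_error = err, n = n, h = h, pressure = sol$pressure,
       analytic = pa, mask = mask, grid = grid)
}

#' Darcy point-source benchmark
#'
#' A constant-rate volumetric source at the centre voxel of a homogeneous
#' medium, solved inside a spherical shell on which the analytic pressure
#' `p = Q/(4 pi K r)` is imposed, so the interior solution can be compared
#' directly with the free-space point-source profile on a mid-field annulus
#' (source-cell discretization decays within a few voxels).
#'
#' @param n cells per axis.
#' @param K scalar hydraulic conductivity \[m^2/(Pa s)\].
#' @param Q volumetric source rate \[m^3/s\].
#' @param h voxel spacing \[m\].
#' @param annulus radii bounds in voxel units for the comparison.
#' @return list: `max_rel_error`, `mean_rel_error` on the annulus, `n`,
#'   `pressure`, `analytic`, `r` (radius array), `mask`.
#' @export
point_source_benchmark <- function(n = 64, K = 1.9e-12, Q = 0.3e-9 / 60,
                                   h = 0.2e-3, annulus = c(5, 15)) {
  ctr0 <- (n + 1L) %/% 2L              # source voxel centre sits exactly at 0
  grid <- voxel_grid(c(n, n, n), rep(h, 3), origin = rep(-(ctr0 - 1L) * h, 3))
  cx <- axis_coords(grid, 1); cy <- axis_coords(grid, 2); cz <- axis_coords(grid, 3)
  r <- sqrt(outer(outer(cx^2, cy^2, `+`), cz^2, `+`))
  R_far <- (min(ctr0, n - ctr0) - 1.5) * h
  mask <- r < R_far
  levelset <- r - R_far
  lmap <- label_map(array(LABEL_TUMOR, dim = grid$shape), cut_ends = character(0))
  kn <- array(0, dim = grid$shape)             # no vascular exchange
  src <- source_field(kn, lmap, tissue_params())
  src$ced[ctr0, ctr0, ctr0] <- Q / grid$voxel_volume
  Karr <- array(K, dim = grid$shape)
  g <- function(x, y, z) Q / (4 * pi * K * sqrt(x^2 + y^2 + z^2))
  sys <- assemble_pressure_system(Karr, src, bcs = NULL, grid = grid,
                                  mask = mask, levelset = levelset,
                                  dirichlet_fun = g,
                                  crossing_fun = .sphere_crossing(R_far))
  sol <- solve_pressure(sys)
  pa <- Q / (4 * pi * K * r)
  ann <- mask & r >= annulus[1] * h & r <= annulus[2] * h
  rel <- abs(sol$pressure[ann] - pa[ann]) / pa[ann]
  list(max_rel_error = max(rel), mean_rel_error = mean(rel), n = n,
       pressure = sol$pressure, analytic = pa, r = r, mask = mask)
}
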