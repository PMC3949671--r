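# Synthetic leg/tumor phantom: geometry, spatially correlated Ktrans and
# porosity fields, and forward-simulated DCE curves.  Emulates the
# statistical structure of DCE-MRI-derived input maps (rim-enhanced
# heterogeneous tumor leakiness, tumor abutting the impermeable skin) so
# every downstream stage is testable without any imaging data.

#' Phantom specification
#'
#' Geometry and field statistics for [make_phantom()].  The tumor is an
#' ellipsoid embedded in an elliptic-cylinder "leg" running along x (the
#' limb axis; the x- and x+ box faces are the cut ends), with one flank
#' within `skin_offset` of the exterior boundary.  Ktrans and porosity are
#' spatially correlated lognormal-like random fields with the requested
#' tissue means and coefficient of variation; tumor Ktrans is rim-enhanced.
#' Defaults (tumor phi 0.40 / host 0.20, tumor Ktrans 0.1 / host 0.01
#' 1/min, rim factor 3, CV 0.3) are literature-typical placeholders — the
#' source study's averages are not published.
#'
#' @param tumor_center \[m\] triple or NULL (auto: mid-x/mid-z, shifted
#'   toward the skin so the flank sits `skin_offset` from the leg surface).
#' @param tumor_radii \[m\] ellipsoid semi-axes.
#' @param skin_offset \[m\] tumor-to-exterior gap.
#' @param ktrans_mean_tumor,ktrans_mean_host mean Ktrans \[1/min\].
#' @param rim_enhancement_factor rim/core Ktrans ratio (>= 1).
#' @param phi_mean_tumor,phi_mean_host mean porosities.
#' @param phi_core_factor core/rim porosity ratio inside the tumor (>= 1):
#'   the necrotic, cell-poor tumor core has an elevated extracellular
#'   fraction, complementary to the perfused rim's Ktrans enhancement.
#' @param heterogeneity_cv coefficient of variation of the Ktrans field.
#' @param phi_heterogeneity_cv coefficient of variation of the porosity
#'   field (ve maps are considerably smoother than Ktrans maps).
#' @param correlation_length \[m\] Gaussian correlation length.
#' @param seed integer; identical seed gives a bit-identical phantom.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(tumor_center = NULL,
                         tumor_radii = c(2.5e-3, 1.5e-3, 1.5e-3),
                         skin_offset = 0.3e-3,
                         ktrans_mean_tumor = 0.1, ktrans_mean_host = 0.01,
                         rim_enhancement_factor = 3,
                         phi_mean_tumor = 0.40, phi_mean_host = 0.20,
                         phi_core_factor = 1.3,
                         heterogeneity_cv = 0.3,
                         phi_heterogeneity_cv = 0.15,
                         correlation_length = 0.5e-3,
                         seed = 42L) {
  stopifnot(length(tumor_radii) == 3L, all(tumor_radii > 0),
            skin_offset >= 0, ktrans_mean_tumor >= 0, ktrans_mean_host >= 0,
            rim_enhancement_factor >= 1, phi_core_factor >= 1,
            phi_mean_tumor > 0, phi_mean_tumor < 1,
            phi_mean_host > 0, phi_mean_host < 1,
            heterogeneity_cv >= 0, phi_heterogeneity_cv >= 0,
            correlation_length > 0)
  structure(list(tumor_center = tumor_center, tumor_radii = tumor_radii,
                 skin_offset = skin_offset,
                 ktrans_mean_tumor = ktrans_mean_tumor,
                 ktrans_mean_host = ktrans_mean_host,
                 rim_enhancement_factor = rim_enhancement_factor,
                 phi_mean_tumor = phi_mean_tumor,
                 phi_mean_host = phi_mean_host,
                 phi_core_factor = phi_core_factor,
                 heterogeneity_cv = heterogeneity_cv,
                 phi_heterogeneity_cv = phi_heterogeneity_cv,
                 correlation_length = correlation_length,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# separable Gaussian smoothing of a 3-D array (dense per-axis kernels,
# truncated at 3 sd, rows renormalized; edge effects are absorbed by the
# per-tissue standardization applied afterwards)
.smooth3 <- function(arr, sd_vox) {
  shape <- dim(arr)
  for (ax in 1:3) {
    s <- sd_vox[ax]
    if (s <= 1e-6) next
    n <- shape[ax]
    off <- outer(seq_len(n), seq_len(n), `-`)
    Ksm <- exp(-off^2 / (2 * s^2))
    Ksm[abs(off) > 3 * s + 1] <- 0
    Ksm <- Ksm / rowSums(Ksm)
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(arr, perm)
    dd <- dim(a)
    a <- Ksm %*% matrix(a, nrow = n)
    arr <- aperm(array(a, dim = dd), order(perm))
  }
  arr
}

# correlated standard field: smoothed white noise, z-scored within `sel`
.corr_field <- function(shape, sd_vox, sel) {
  f <- .smooth3(array(stats::rnorm(prod(shape)), dim = shape), sd_vox)
  mu <- mean(f[sel]); s <- stats::sd(f[sel])
  if (!is.finite(s) || s == 0) s <- 1
  (f - mu) / s
}

#' Generate a synthetic leg/tumor phantom
#'
#' @param spec a [phantom_spec].
#' @param grid a [voxel_grid] (see [default_grid()]).
#' @return A [ced_maps]: labels (exterior / host / tumor, cut ends at
#'   x- and x+), Ktrans \[1/s\] (0 in exterior) and porosity (NA sentinel in
#'   exterior).  Tissue-wise empirical means match the requested means (Ktrans
#'   exactly by affine rescale; porosity within clipping tolerance).
#' @export
make_phantom <- function(spec, grid = default_grid(2L)) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(grid, "voxel_grid"))
  shape <- grid$shape
  cx <- axis_coords(grid, 1); cy <- axis_coords(grid, 2); cz <- axis_coords(grid, 3)
  ext <- grid$extent
  leg_c <- grid$origin - grid$spacing / 2 + ext / 2   # box centre
  leg_r <- c(NA, 0.42 * ext[2], 0.40 * ext[3])        # elliptic cylinder radii
  Y <- array(rep(cy, each = shape[1]), dim = shape)
  Z <- array(rep(cz, each = shape[1] * shape[2]), dim = shape)
  X <- array(cx, dim = shape)
  leg <- ((Y - leg_c[2]) / leg_r[2])^2 + ((Z - leg_c[3]) / leg_r[3])^2 <= 1

  tc <- spec$tumor_center
  if (is.null(tc)) {
    tc <- c(leg_c[1], leg_c[2] + leg_r[2] - spec$tumor_radii[2] - spec$skin_offset,
            leg_c[3])
  }
  u2 <- ((X - tc[1]) / spec$tumor_radii[1])^2 +
        ((Y - tc[2]) / spec$tumor_radii[2])^2 +
        ((Z - tc[3]) / spec$tumor_radii[3])^2
  tumor <- u2 <= 1
  if (any(tumor & !leg)) {
    stop(errorCondition("tumor ellipsoid extends outside the leg tissue region",
                        class = "cedsim_phantom_error"))
  }
  if (!any(tumor)) stop("tumor ellipsoid contains no voxels at this resolution")
  labels <- array(LABEL_EXTERIOR, dim = shape)
  labels[leg] <- LABEL_HOST
  labels[tumor] <- LABEL_TUMOR
  lmap <- label_map(labels, cut_ends = c("x-", "x+"))

  sd_vox <- spec$correlation_length / grid$spacing
  cv_k <- spec$heterogeneity_cv
  cv_p <- spec$phi_heterogeneity_cv
  ktrans <- array(0, dim = shape)
  phi <- array(NA_real_, dim = shape)
  host <- labels == LABEL_HOST
  rim_w <- pmin(pmax((sqrt(u2) - 0.55) / 0.30, 0), 1)   # 0 core -> 1 rim

  withr::with_seed(spec$seed, {
    zk <- if (cv_k > 0) .corr_field(shape, sd_vox, leg) else array(0, dim = shape)
    zp <- if (cv_p > 0) .corr_field(shape, sd_vox, leg) else array(0, dim = shape)
    for (tissue in c("tumor", "host")) {
      sel <- if (tissue == "tumor") tumor else host
      km <- spec[[paste0("ktrans_mean_", tissue)]] / 60    # 1/min -> 1/s
      pm <- spec[[paste0("phi_mean_", tissue)]]
      k <- pmax(km * (1 + cv_k * zk[sel]), 0)
      if (tissue == "tumor" && spec$rim_enhancement_factor > 1) {
        # perfused rim: elevated leakiness
        k <- k * (1 + (spec$rim_enhancement_factor - 1) * rim_w[sel])
      }
      if (mean(k) > 0) k <- k * km / mean(k)               # exact tissue mean
      ktrans[sel] <- k
      p <- pmax(pm * (1 + cv_p * zp[sel]), 0.01)
      if (tissue == "tumor" && spec$phi_core_factor > 1) {
        # necrotic, cell-poor core: elevated extracellular fraction
        p <- p * (1 + (spec$phi_core_factor - 1) * (1 - rim_w[sel]))
      }
      if (mean(p) > 0) p <- p * pm / mean(p)
      phi[sel] <- pmin(pmax(p, 0.01), 0.95)
    }
  })
  ced_maps(grid, lmap, ktrans, phi)
}

#' Biexponential arterial input function
#'
#' `Cp(t) = A1 exp(-m1 t) + A2 exp(-m2 t)` with amplitudes in mM and decay
#' rates in 1/min (converted internally when evaluated at seconds).  A
#' population-style curve: the fast term is distribution/renal clearance,
#' the slow term body washout.
#'
#' @param A1,A2 amplitudes \[mM\], >= 0.
#' @param m1,m2 decay rates \[1/min\], >= 0.
#' @return object of class `aif_model`.
#' @export
aif_model <- function(A1 = 3.0, m1 = 0.25, A2 = 0.7, m2 = 0.015) {
  stopifnot(A1 >= 0, A2 >= 0, m1 >= 0, m2 >= 0)
  structure(list(A = c(A1, A2), m = c(m1, m2)), class = "aif_model")
}

#' Evaluate an AIF at times in seconds
#' @param aif an [aif_model].
#' @param times \[s\].
#' @return plasma concentration \[mM\].
#' @export
aif_conc <- function(aif, times) {
  m_s <- aif$m / 60
  aif$A[1] * exp(-m_s[1] * times) + aif$A[2] * exp(-m_s[2] * times)
}

#' DCE concentration time series container
#'
#' @param times \[s\] vector.
#' @param conc matrix (voxels x times) of tissue concentrations \[mM\].
#' @param shape optional 3-D shape of the voxel set.
#' @return object of class `dce_series`.
#' @export
dce_series <- function(times, conc, shape = NULL) {
  conc <- as.matrix(conc)
  stopifnot(ncol(conc) == length(times))
  structure(list(times = times, conc = conc, shape = shape),
            class = "dce_series")
}

#' Forward-simulate noise-free DCE curves
#'
#' Solves the two-compartment exchange model `dCt/dt = Ktrans Cp(t) -
#' (Ktrans/phi) Ct`, `Ct(0) = 0`, per voxel, using the closed-form
#' biexponential-AIF convolution (see [dce_model_curve()]).  Linear in the
#' AIF amplitudes.
#'
#' @param ktrans vector/array of Ktrans \[1/s\] (>= 0).
#' @param phi vector/array of porosity, > 0.
#' @param aif an [aif_model].
#' @param times \[s\], increasing from 0.
#' @return a [dce_series] (voxels in the input order).
#' @export
forward_dce <- function(ktrans, phi, aif, times) {
  if (is.unsorted(times, strictly = TRUE) || times[1] < 0) {
    stop("times must be strictly increasing and start at >= 0")
  }
  shape <- if (length(dim(ktrans)) == 3L) dim(ktrans) else NULL
  kt <- as.numeric(ktrans); ph <- as.numeric(phi)
  if (any(ph <= 0 | is.na(ph))) stop("phi must be > 0 for forward DCE")
  if (any(kt < 0)) stop("ktrans must be >= 0")
  conc <- matrix(0, length(kt), length(times))
  for (v in seq_along(kt)) {
    conc[v, ] <- dce_model_curve(kt[v], ph[v], aif, times)
  }
  dce_series(times, conc, shape = shape)
}

#' Add i.i.d. Gaussian measurement noise to DCE curves
#'
#' Negative values are retained (concentration estimates from MR signal can
#' undershoot); reproducible for a fixed seed.
#'
#' @param series a [dce_series].
#' @param sigma noise SD \[mM\], >= 0.
#' @param seed integer.
#' @return a [dce_series].
#' @export
add_noise <- function(series, sigma, seed) {
  stopifnot(inherits(series, "dce_series"), sigma >= 0)
  if (sigma == 0) return(series)
  noisy <- withr::with_seed(as.integer(seed), {
    series$conc + stats::rnorm(length(series$conc), sd = sigma)
  })
  dce_series(series$times, noisy, shape = series$shape)
}
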