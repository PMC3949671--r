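# Porosity-dependent constitutive laws (hydraulic conductivity, effective
# diffusivity) and the linearized Starling / lymphatic source terms.

#' Porosity-dependent hydraulic conductivity
#'
#' `K(x) = M_t * phi(x)^gamma` per tissue, with the scaling `M_t =
#' K0_t / phi0_t^gamma` chosen so that `K = K0_t` where `phi = phi0_t`
#' (matching the average tissue conductivity at the average porosity).
#' Exterior voxels get the constant `K0_exterior` regardless of porosity or
#' `gamma` — a low-conductance material realising skin impermeability.
#'
#' @param phi 3-D porosity array (NA sentinel allowed in exterior voxels).
#' @param lmap a [label_map].
#' @param params a [tissue_params].
#' @param gamma conductivity-porosity exponent; defaults to `params$gamma`.
#' @return 3-D array of hydraulic conductivity \[m^2/(Pa s)\].
#' @export
conductivity_map <- function(phi, lmap, params, gamma = params$gamma) {
  lab <- lmap$labels
  if (gamma < 0) stop("gamma must be >= 0")
  tis <- lab != LABEL_EXTERIOR
  if (any(tis & (is.na(phi) | phi <= 0 | phi > 1))) {
    stop("tissue porosity must lie in (0,1]")
  }
  K <- array(params$K0_exterior, dim = dim(lab))
  for (tissue in c("tumor", "host")) {
    t <- tissue_of(params, tissue)
    if (t$phi0 <= 0) stop("phi0 must be > 0")
    sel <- lab == if (tissue == "tumor") LABEL_TUMOR else LABEL_HOST
    K[sel] <- (t$K0 / t$phi0^gamma) * phi[sel]^gamma
  }
  K
}

#' Effective diffusivity in porous tissue
#'
#' `D_eff = D_free * phi^n` (isotropic, empirical exponent `n = 1` by
#' default).  Exterior voxels get `D_eff = 0`: no diffusive transport
#' through air.
#'
#' @inheritParams conductivity_map
#' @return 3-D array of effective diffusivity \[m^2/s\].
#' @export
effective_diffusivity <- function(phi, lmap, params) {
  lab <- lmap$labels
  tis <- lab != LABEL_EXTERIOR
  if (any(tis & (is.na(phi) | phi <= 0 | phi > 1))) {
    stop("tissue porosity must lie in (0,1]")
  }
  D <- array(0, dim = dim(lab))
  D[tis] <- params$D_free * phi[tis]^params$n_diff
  D
}

#' Normalized Ktrans map
#'
#' Ktrans divided by its tissue-wise average (tumor voxels by the tumor
#' average, host voxels by the host average), so the tissue-wise mean of the
#' result is 1.  Used to scale the Starling filtration term for leakiness
#' heterogeneity.  Exterior voxels are 0.
#'
#' @param ktrans 3-D array \[1/s\].
#' @param lmap a [label_map].
#' @return list with `ktrans_norm` (3-D array), `avg_tumor`, `avg_host`.
#' @export
normalize_ktrans <- function(ktrans, lmap) {
  lab <- lmap$labels
  kn <- array(0, dim = dim(lab))
  avg <- c(tumor = NA_real_, host = NA_real_)
  for (tissue in c("tumor", "host")) {
    sel <- lab == if (tissue == "tumor") LABEL_TUMOR else LABEL_HOST
    if (any(sel)) {
      a <- mean(ktrans[sel])
      avg[tissue] <- a
      kn[sel] <- if (a > 0) ktrans[sel] / a else 0
    }
  }
  list(ktrans_norm = kn, avg_tumor = unname(avg["tumor"]),
       avg_host = unname(avg["host"]))
}

#' Linearized volumetric source terms for the pressure equation
#'
#' The continuity equation's right-hand side per unit tissue volume is
#' `Phi_v * ktrans_norm - lymph * (p - p_L)` plus the CED source, where
#' Starling's law gives `Phi_v = Lp (S/V) (p_v - p - sigma (pi_v - pi_i))`.
#' Both terms are affine in pressure, so they are stored as coefficients
#' `a - b p` \[1/s\]: `a = Lp (S/V) ktn (p_v - sigma dpi) + lymph p_L`,
#' `b = Lp (S/V) ktn + lymph`.  The lymphatic sink acts in host tissue
#' only; vascular coefficients are zero in exterior voxels.
#'
#' @param ktrans_norm 3-D normalized Ktrans array (see [normalize_ktrans()]).
#' @param lmap a [label_map].
#' @param params a [tissue_params].
#' @param protocol optional [infusion_protocol]; adds the CED source
#'   `Q / V_voxel` \[1/s\] at the infusion voxel.
#' @param grid required with `protocol`, to supply the voxel volume.
#' @return An object of class `source_field`: arrays `a` \[1/s\],
#'   `b` \[1/(Pa s)\], `lymph` \[1/(Pa s)\], `ced` \[1/s\].
#' @export
source_field <- function(ktrans_norm, lmap, params, protocol = NULL,
                         grid = NULL) {
  lab <- lmap$labels
  a <- array(0, dim = dim(lab))
  b <- array(0, dim = dim(lab))
  lymph <- array(0, dim = dim(lab))
  for (tissue in c("tumor", "host")) {
    t <- tissue_of(params, tissue)
    sel <- lab == if (tissue == "tumor") LABEL_TUMOR else LABEL_HOST
    LpSV <- t$Lp * t$SV
    a[sel] <- LpSV * ktrans_norm[sel] * (params$p_v - t$sigma * (params$pi_v - t$pi_i))
    b[sel] <- LpSV * ktrans_norm[sel]
  }
  lymph[lab == LABEL_HOST] <- params$lymph_coeff
  a <- a + lymph * params$p_L
  b <- b + lymph
  ced <- array(0, dim = dim(lab))
  if (!is.null(protocol)) {
    stopifnot(inherits(grid, "voxel_grid"))
    .check_site(protocol, lmap)
    s <- protocol$site
    ced[s[1], s[2], s[3]] <- protocol$Q / grid$voxel_volume
  }
  structure(list(a = a, b = b, lymph = lymph, ced = ced),
            class = "source_field")
}

#' Starling filtration rate at a given pressure field
#'
#' Evaluates `Phi_v * ktrans_norm = Lp (S/V) ktn (p_v - p - sigma (pi_v -
#' pi_i))` \[1/s\]; zero in exterior voxels.  Affine and decreasing in `p`
#' (the stabilising sign that keeps the pressure system well posed).
#'
#' @param p 3-D pressure array \[Pa\].
#' @inheritParams source_field
#' @return 3-D array \[1/s\].
#' @export
starling_source <- function(p, ktrans_norm, lmap, params) {
  lab <- lmap$labels
  out <- array(0, dim = dim(lab))
  for (tissue in c("tumor", "host")) {
    t <- tissue_of(params, tissue)
    sel <- lab == if (tissue == "tumor") LABEL_TUMOR else LABEL_HOST
    out[sel] <- t$Lp * t$SV * ktrans_norm[sel] *
      (params$p_v - p[sel] - t$sigma * (params$pi_v - t$pi_i))
  }
  out
}
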