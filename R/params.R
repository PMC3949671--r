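# Scalar parameter registry (tissue/vascular constants) and infusion protocol.

#' Tissue and vascular parameters
#'
#' The scalar registry for the porous-media model.  Defaults are the
#' simulation values for the KHT hind-limb sarcoma system: vessel
#' permeability `Lp` \[m/(Pa s)\] and vascular area density `SV` \[1/m\] per
#' tissue, the lymphatic filtration coefficient (host tissue only, tumors
#' lack functional lymphatics), microvascular/lymphatic/osmotic pressures
#' \[Pa\], reflection coefficients, baseline hydraulic conductivities `K0`
#' \[m^2/(Pa s)\] (the exterior value is ~2 orders of magnitude below host,
#' realising skin impermeability), average porosities `phi0`, the
#' conductivity-porosity exponent `gamma` (Carman-Kozeny-like baseline 3),
#' albumin free diffusivity `D_free` \[m^2/s\] and the porous-diffusion
#' exponent `n_diff` (= 1).
#'
#' @param ... named overrides of any default listed above.
#' @return An object of class `tissue_params`.
#' @examples
#' p <- tissue_params(gamma = 5)
#' effective_pressure(p, "tumor")   # Starling equilibrium pressure [Pa]
#' @export
tissue_params <- function(...) {
  p <- list(
    Lp_tumor = 2e-11, Lp_host = 3e-12,          # m/(Pa s)
    SV_tumor = 20000, SV_host = 7000,           # 1/m
    lymph_coeff = 1e-7,                         # 1/(Pa s), host only
    p_v = 2300, p_L = 0,                        # Pa
    pi_v = 2670, pi_i_tumor = 3230, pi_i_host = 1330,  # Pa
    sigma_tumor = 0.82, sigma_host = 0.91,
    K0_tumor = 1.9e-12, K0_host = 3.8e-13, K0_exterior = 7.7e-15,
    phi0_tumor = 0.40, phi0_host = 0.20,
    gamma = 3,
    D_free = 5.8e-11,                           # m^2/s
    n_diff = 1
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(p))
  if (length(unknown)) stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  p[names(ov)] <- ov
  with(p, {
    if (any(c(Lp_tumor, Lp_host, K0_tumor, K0_host, K0_exterior, D_free) <= 0))
      stop("conductivities, permeabilities and diffusivities must be > 0")
    if (phi0_tumor <= 0 || phi0_tumor >= 1 || phi0_host <= 0 || phi0_host >= 1)
      stop("average porosities must lie in (0,1)")
    if (sigma_tumor < 0 || sigma_tumor > 1 || sigma_host < 0 || sigma_host > 1)
      stop("reflection coefficients must lie in [0,1]")
    if (gamma < 0) stop("gamma must be >= 0")
  })
  structure(p, class = "tissue_params")
}

#' Per-tissue parameter lookup
#'
#' @param params a [tissue_params] object.
#' @param tissue `"tumor"` or `"host"`.
#' @return named list with `Lp`, `SV`, `sigma`, `pi_i`, `K0`, `phi0`.
#' @export
tissue_of <- function(params, tissue = c("tumor", "host")) {
  tissue <- match.arg(tissue)
  list(Lp = params[[paste0("Lp_", tissue)]],
       SV = params[[paste0("SV_", tissue)]],
       sigma = params[[paste0("sigma_", tissue)]],
       pi_i = params[[paste0("pi_i_", tissue)]],
       K0 = params[[paste0("K0_", tissue)]],
       phi0 = params[[paste0("phi0_", tissue)]])
}

#' Starling effective pressure
#'
#' The interstitial pressure at which transvascular filtration vanishes,
#' `p_eff = p_v - sigma * (pi_v - pi_i)`.  With tumor defaults this is
#' 2300 - 0.82*(2670 - 3230) = 2759.2 Pa.
#'
#' @inheritParams tissue_of
#' @return scalar \[Pa\].
#' @export
effective_pressure <- function(params, tissue = c("tumor", "host")) {
  t <- tissue_of(params, tissue)
  params$p_v - t$sigma * (params$pi_v - t$pi_i)
}

#' Infusion protocol
#'
#' @param site integer voxel index triple (1-based array indices) of the
#'   infusion voxel; must be a tissue voxel, never exterior.
#' @param Q_uL_min infusion flow rate in uL/min (converted to m^3/s
#'   internally); baseline 0.3.
#' @param duration infusion duration \[s\].
#' @param output_times times \[s\] at which the tracer field is recorded.
#' @return An object of class `infusion_protocol` with `Q` in m^3/s.
#' @export
infusion_protocol <- function(site, Q_uL_min = 0.3, duration = 3600,
                              output_times = c(900, 3600)) {
  site <- as.integer(site)
  stopifnot(length(site) == 3L, Q_uL_min >= 0, duration >= 0)
  structure(list(site = site,
                 Q = Q_uL_min * 1e-9 / 60,   # uL/min -> m^3/s
                 Q_uL_min = Q_uL_min,
                 duration = duration,
                 output_times = sort(unique(output_times))),
            class = "infusion_protocol")
}

.check_site <- function(protocol, lmap) {
  s <- protocol$site
  lab <- lmap$labels[s[1], s[2], s[3]]
  if (lab == LABEL_EXTERIOR) {
    stop(errorCondition("infusion site voxel is EXTERIOR", class = "cedsim_site_error"))
  }
  invisible(lab)
}

#' Read a run configuration file
#'
#' A single YAML file with optional sections `grid`, `tissue`, `phantom`,
#' `infusion`, `solver`, `analysis`; every [tissue_params] scalar is
#' overridable under `tissue`.  Unknown keys raise errors rather than being
#' ignored.
#'
#' @param path YAML file path.
#' @return list with elements `grid` ([voxel_grid]), `params`
#'   ([tissue_params]), `phantom` ([phantom_spec]), `protocol`
#'   ([infusion_protocol]), `solver`, `analysis` (lists of options).
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  g <- cfg$grid
  grid <- if (is.null(g)) default_grid()
          else if (!is.null(g$scale)) default_grid(g$scale)
          else voxel_grid(unlist(g$shape), unlist(g$spacing_mm) * 1e-3)
  params <- do.call(tissue_params, as.list(cfg$tissue))
  phantom <- do.call(phantom_spec, as.list(cfg$phantom))
  protocol <- if (is.null(cfg$infusion)) NULL else {
    inf <- cfg$infusion
    infusion_protocol(site = unlist(inf$site),
                      Q_uL_min = inf$Q_uL_min %||% 0.3,
                      duration = inf$duration %||% 3600,
                      output_times = unlist(inf$output_times) %||% c(900, 3600))
  }
  list(grid = grid, params = params, phantom = phantom, protocol = protocol,
       solver = cfg$solver %||% list(), analysis = cfg$analysis %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a provenance record for a run
#'
#' @param path output JSON path.
#' @param config_path optional config file (its md5 is recorded).
#' @param seed RNG seed used, if any.
#' @param extra named list of extra fields.
#' @export
write_provenance <- function(path, config_path = NULL, seed = NULL,
                             extra = list()) {
  rec <- c(list(
    package = "cedsim",
    version = as.character(utils::packageVersion("cedsim")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config_path,
    config_md5 = if (!is.null(config_path)) unname(tools::md5sum(config_path)),
    seed = seed
  ), extra)
  jsonlite::write_json(rec[!vapply(rec, is.null, logical(1))], path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
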