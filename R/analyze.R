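# Distribution-volume analysis and the parameter-study driver.

#' Tracer distribution volume at one time point
#'
#' The distribution volume is the tissue volume occupied by voxels whose
#' normalized concentration exceeds `threshold_fraction` (default 15%) of
#' the maximum tissue concentration (which is the held infusion voxel's
#' value, 1, during infusion).  Only non-exterior voxels count; the
#' tumor-restricted count gives the tumor coverage fraction.
#'
#' @param c_arr 3-D normalized concentration array.
#' @param lmap a [label_map].
#' @param grid a [voxel_grid].
#' @param threshold_fraction fraction of the maximum, default 0.15.
#' @return list: `Vd_whole`, `Vd_tumor` \[m^3\], `coverage`
#'   (= Vd_tumor / tumor volume), `threshold` (absolute), `tumor_volume`.
#' @export
distribution_volume <- function(c_arr, lmap, grid, threshold_fraction = 0.15) {
  lab <- lmap$labels
  tis <- lab != LABEL_EXTERIOR
  tum <- lab == LABEL_TUMOR
  cmax <- if (any(tis)) max(c_arr[tis]) else 0
  thr <- threshold_fraction * cmax
  V <- grid$voxel_volume
  if (cmax <= 0) {
    return(list(Vd_whole = 0, Vd_tumor = 0, coverage = 0, threshold = 0,
                tumor_volume = sum(tum) * V))
  }
  hot <- c_arr > thr
  Vd_whole <- sum(hot & tis) * V
  Vd_tumor <- sum(hot & tum) * V
  tumor_volume <- sum(tum) * V
  list(Vd_whole = Vd_whole, Vd_tumor = Vd_tumor,
       coverage = if (tumor_volume > 0) Vd_tumor / tumor_volume else NA_real_,
       threshold = thr, tumor_volume = tumor_volume)
}

#' Fit the distribution-volume vs infusion-volume relationship
#'
#' Whole-leg spread grows linearly with infusion volume (`Vd = a + b Vi`,
#' ordinary least squares); tumor spread saturates and is fit with the
#' through-origin exponential `Vd = Vmax (1 - exp(-Vi / tau))` by bounded
#' Levenberg-Marquardt with a small multistart.
#'
#' @param vi infusion volumes \[m^3\] (>= 3 distinct values).
#' @param vd distribution volumes \[m^3\].
#' @param model `"linear"` or `"exponential"`.
#' @return list: for linear `slope`, `intercept`, `r_squared`; for
#'   exponential `Vmax`, `tau`, `r_squared`.
#' @export
fit_vd_vi <- function(vi, vd, model = c("linear", "exponential")) {
  model <- match.arg(model)
  stopifnot(length(vi) == length(vd))
  if (length(vi) < 3L || length(unique(vi)) < 2L) {
    stop(errorCondition("need >= 3 points with non-constant Vi",
                        class = "cedsim_fit_error"))
  }
  sst <- sum((vd - mean(vd))^2)
  if (model == "linear") {
    fit <- stats::lm(vd ~ vi)
    ssr <- sum(stats::residuals(fit)^2)
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = if (sst > 0) 1 - ssr / sst else 1)
  } else {
    span <- max(vi) - min(vi)
    starts <- rbind(c(max(vd), span / 3),
                    c(2 * max(vd), span),
                    c(max(vd) * 1.2, span / 10))
    best <- NULL
    for (s in seq_len(nrow(starts))) {
      fit <- tryCatch(
        minpack.lm::nls.lm(
          par = c(Vmax = starts[s, 1], tau = starts[s, 2]),
          lower = c(1e-300, 1e-300), upper = c(Inf, Inf),
          fn = function(par) par[1] * (1 - exp(-vi / par[2])) - vd,
          control = minpack.lm::nls.lm.control(maxiter = 500)),
        error = function(e) NULL)
      if (is.null(fit)) next
      ssr <- sum(fit$fvec^2)
      if (is.null(best) || ssr < best$ssr) {
        best <- list(Vmax = unname(fit$par[1]), tau = unname(fit$par[2]),
                     ssr = ssr)
      }
    }
    if (is.null(best)) stop("exponential Vd-Vi fit failed from all starts")
    list(Vmax = best$Vmax, tau = best$tau,
         r_squared = if (sst > 0) 1 - best$ssr / sst else 1)
  }
}

#' Tracer centre-of-mass offset from the infusion site
#'
#' Euclidean distance \[m\] between the concentration-weighted centre of
#' mass (tissue voxels) and the infusion voxel centre — the asymmetry
#' metric for heterogeneous-porosity distributions.
#'
#' @param c_arr 3-D normalized concentration array.
#' @param lmap a [label_map].
#' @param grid a [voxel_grid].
#' @param site infusion voxel index triple.
#' @return list `offset_m`, `offset_voxels` (in units of mean in-plane
#'   spacing), `com` \[m\].
#' @export
tracer_com_offset <- function(c_arr, lmap, grid, site) {
  tis <- lmap$labels != LABEL_EXTERIOR
  w <- c_arr * tis
  tot <- sum(w)
  coords <- lapply(1:3, function(a) axis_coords(grid, a))
  shape <- grid$shape
  X <- array(coords[[1]], dim = shape)
  Y <- array(rep(coords[[2]], each = shape[1]), dim = shape)
  Z <- array(rep(coords[[3]], each = shape[1] * shape[2]), dim = shape)
  com <- c(sum(w * X), sum(w * Y), sum(w * Z)) / tot
  sc <- c(coords[[1]][site[1]], coords[[2]][site[2]], coords[[3]][site[3]])
  off <- sqrt(sum((com - sc)^2))
  list(offset_m = off, offset_voxels = off / mean(grid$spacing[1:2]), com = com)
}

# ---- catheter-site presets -------------------------------------------------

#' Catheter-site presets
#'
#' `site_tumor_centroid`: tumor voxel nearest the tumor centre of mass.
#' `site_interface`: tumor voxel with a host 6-neighbour nearest the
#' centroid-to-skin axis (the dorsal interface).
#' `site_anterior`: most-anterior tumor voxel (largest x, the limb axis),
#' nearest the axis through the centroid.
#'
#' @param lmap a [label_map].
#' @return integer voxel index triple.
#' @export
site_tumor_centroid <- function(lmap) {
  idx <- which(lmap$labels == LABEL_TUMOR, arr.ind = TRUE)
  if (!nrow(idx)) stop("no tumor voxels")
  ctr <- colMeans(idx)
  idx[which.min(rowSums(sweep(idx, 2, ctr)^2)), ]
}

.tumor_host_interface <- function(lmap) {
  lab <- lmap$labels
  shape <- dim(lab)
  idx <- which(lab == LABEL_TUMOR, arr.ind = TRUE)
  has_host <- logical(nrow(idx))
  for (ax in 1:3) {
    for (s in c(-1L, 1L)) {
      nb <- idx
      nb[, ax] <- nb[, ax] + s
      ok <- nb[, ax] >= 1L & nb[, ax] <= shape[ax]
      lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * shape[1] +
        (nb[ok, 3] - 1L) * shape[1] * shape[2]
      has_host[ok] <- has_host[ok] | lab[lin] == LABEL_HOST
    }
  }
  idx[has_host, , drop = FALSE]
}

#' @rdname site_tumor_centroid
#' @export
site_interface <- function(lmap) {
  surf <- .tumor_host_interface(lmap)
  if (!nrow(surf)) stop("tumor has no host-adjacent surface")
  ctr <- colMeans(which(lmap$labels == LABEL_TUMOR, arr.ind = TRUE))
  # nearest the vertical (y) axis through the centroid, i.e. the skin axis
  d2 <- (surf[, 1] - ctr[1])^2 + (surf[, 3] - ctr[3])^2
  surf[which.min(d2), ]
}

#' @rdname site_tumor_centroid
#' @export
site_anterior <- function(lmap) {
  idx <- which(lmap$labels == LABEL_TUMOR, arr.ind = TRUE)
  ctr <- colMeans(idx)
  xmax <- max(idx[, 1])
  cand <- idx[idx[, 1] == xmax, , drop = FALSE]
  d2 <- (cand[, 2] - ctr[2])^2 + (cand[, 3] - ctr[3])^2
  cand[which.min(d2), ]
}

# ---- parameter study -------------------------------------------------------

#' Run a single CED simulation and summarise it
#'
#' Flow solve + infusion + distribution volumes at each output time.
#'
#' @param maps a [ced_maps].
#' @param params a [tissue_params].
#' @param protocol an [infusion_protocol].
#' @param gamma conductivity exponent.
#' @param dt transport time step \[s\].
#' @param threshold_fraction Vd threshold.
#' @return list: `flow`, `tracer`, `table` (one row per output time with
#'   Vi, Vd, coverage, peak IFP/speed, centre-of-mass offset).
#' @export
run_ced_case <- function(maps, params, protocol, gamma = params$gamma,
                         dt = 5, threshold_fraction = 0.15) {
  flow <- solve_flow(maps, params, protocol = protocol, gamma = gamma)
  tracer <- run_infusion(maps, params, flow, protocol, dt = dt)
  rows <- lapply(seq_along(tracer$times), function(i) {
    dv <- distribution_volume(tracer$c_norm[[i]], maps$labels, maps$grid,
                              threshold_fraction)
    off <- tracer_com_offset(tracer$c_norm[[i]], maps$labels, maps$grid,
                             protocol$site)
    data.frame(time = tracer$times[i],
               Vi = protocol$Q * tracer$times[i],
               Vd_whole = dv$Vd_whole, Vd_tumor = dv$Vd_tumor,
               coverage = dv$coverage,
               extra_tumoral_fraction =
                 if (dv$Vd_whole > 0) 1 - dv$Vd_tumor / dv$Vd_whole else NA_real_,
               peak_ifp_tumor = flow$peak_ifp_tumor,
               peak_speed = flow$peak_speed,
               com_offset_voxels = off$offset_voxels,
               mass_mismatch_max = max(tracer$mass$mismatch_rel))
  })
  list(flow = flow, tracer = tracer, table = do.call(rbind, rows))
}

#' Flow-rate / catheter-site / conductivity parameter study
#'
#' One-at-a-time variation around the baseline (centre infusion, 0.3
#' uL/min, baseline gamma), as in the sensitivity analysis this package
#' reproduces: three flow rates, three catheter sites, three gamma values.
#' All runs share the identical phantom.  Output times per run include the
#' requested checkpoints plus the times at which each flow rate reaches the
#' reference infusion volume (so coverages can be compared at matched Vi).
#' A failed run is marked and the study continues.
#'
#' @param maps a [ced_maps].
#' @param params a [tissue_params].
#' @param flow_rates \[uL/min\] values; first is baseline.
#' @param sites named list of voxel index triples; first is baseline.
#' @param gammas conductivity exponents; first is baseline.
#' @param duration \[s\].
#' @param output_times \[s\] checkpoints for every run.
#' @param dt transport step \[s\].
#' @param threshold_fraction Vd threshold.
#' @return object of class `ced_study`: `results` (tidy data.frame, one row
#'   per run x time), `runs` (per-run summaries incl. errors), `vi_ref`
#'   \[m^3\].
#' @export
run_parameter_study <- function(maps, params,
                                flow_rates = c(0.3, 1, 3),
                                sites = NULL,
                                gammas = c(3, 5, 10),
                                duration = 3600,
                                output_times = seq(360, 3600, by = 360),
                                dt = 5,
                                threshold_fraction = 0.15) {
  if (is.null(sites)) {
    sites <- list(center = site_tumor_centroid(maps$labels),
                  interface = site_interface(maps$labels),
                  anterior = site_anterior(maps$labels))
  }
  base_q <- flow_rates[1]
  vi_ref <- base_q * 1e-9 / 60 * duration
  cases <- list()
  for (q in flow_rates) {
    cases[[length(cases) + 1L]] <- list(Q = q, site = names(sites)[1],
                                        gamma = gammas[1])
  }
  for (sn in names(sites)[-1]) {
    cases[[length(cases) + 1L]] <- list(Q = base_q, site = sn, gamma = gammas[1])
  }
  for (g in gammas[-1]) {
    cases[[length(cases) + 1L]] <- list(Q = base_q, site = names(sites)[1],
                                        gamma = g)
  }
  results <- list(); runs <- list()
  for (ci in seq_along(cases)) {
    cs <- cases[[ci]]
    t_match <- vi_ref / (cs$Q * 1e-9 / 60)
    ot <- sort(unique(c(output_times, min(t_match, duration))))
    ot <- ot[ot <= duration]
    protocol <- infusion_protocol(sites[[cs$site]], Q_uL_min = cs$Q,
                                  duration = duration, output_times = ot)
    run <- tryCatch(
      run_ced_case(maps, params, protocol, gamma = cs$gamma, dt = dt,
                   threshold_fraction = threshold_fraction),
      error = function(e) e)
    if (inherits(run, "error")) {
      runs[[ci]] <- list(case = cs, ok = FALSE, error = conditionMessage(run))
      next
    }
    tb <- run$table
    tb$Q_uL_min <- cs$Q; tb$site <- cs$site; tb$gamma <- cs$gamma
    tb$at_matched_vi <- abs(tb$time - t_match) < dt
    results[[length(results) + 1L]] <- tb
    runs[[ci]] <- list(case = cs, ok = TRUE, table = tb,
                       peak_ifp_tumor = run$flow$peak_ifp_tumor,
                       peak_speed = run$flow$peak_speed)
  }
  structure(list(results = do.call(rbind, results), runs = runs,
                 vi_ref = vi_ref, sites = sites),
            class = "ced_study")
}

#' @method print ced_study
#' @export
print.ced_study <- function(x, ...) {
  ok <- vapply(x$runs, function(r) isTRUE(r$ok), logical(1))
  cat(sprintf("<ced_study> %d/%d runs ok; %d result rows\n",
              sum(ok), length(ok),
              if (is.null(x$results)) 0L else nrow(x$results)))
  invisible(x)
}
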