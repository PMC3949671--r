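# Transient albumin tracer transport on the frozen steady flow field.
#
# Conservative finite volumes for  d(phi c)/dt + div(v c - D_eff grad c) =
# -s(x) c : first-order upwind advection on the face Darcy fluxes,
# harmonic-mean face diffusivity, concentration held at the normalized
# value 1 at the infusion voxel, advective outflow (zero diffusive flux) at
# the Dirichlet-pressure cut ends, no flux elsewhere.  s(x) >= 0 [1/s] is
# the fluid drainage rate (lymphatics plus net capillary reabsorption where
# CED raises pressure above the Starling equilibrium): tracer leaves with
# the draining fluid at the local pore concentration.  Wherever filtration
# adds tracer-free fluid, dilution is automatic in the conservative form.
# This pairing of the tracer equation with the divergence of the flow field
# is what makes the operator an M-matrix, so backward Euler on both
# advection and diffusion is monotone (discrete maximum principle, c in
# [0,1] exactly) and unconditionally stable; the matrix is factorized once
# per run and reused at every step.

#' Build the transport operator for a frozen flow field
#'
#' @param flow a `flow_field` from [solve_flow()] (face fluxes are used),
#'   or any list with `fx`, `fy`, `fz` face-flux arrays \[m^3/s\].
#' @param D_eff 3-D effective diffusivity array \[m^2/s\] (0 in exterior).
#' @param phi 3-D porosity array (NA sentinel in exterior -> effective 1).
#' @param grid a [voxel_grid].
#' @param site integer triple: infusion voxel (held at c = 1).
#' @param dt time step \[s\].
#' @param sink_rate optional 3-D array \[1/s\]: fluid drainage rate at which
#'   tracer is removed with the absorbed fluid (lymphatics + net capillary
#'   reabsorption); >= 0, default 0.
#' @return An object of class `transport_operator` (factorized system plus
#'   the flux bookkeeping needed for the per-step mass audit).
#' @export
transport_operator <- function(flow, D_eff, phi, grid, site, dt,
                               sink_rate = NULL) {
  stopifnot(inherits(grid, "voxel_grid"), dt > 0)
  shape <- grid$shape
  N <- prod(shape)
  V <- grid$voxel_volume
  phie <- phi
  phie[is.na(phie)] <- 1
  if (any(phie <= 0)) stop("porosity must be > 0 (exterior sentinel NA allowed)")
  phiV <- as.numeric(phie) * V
  s_lin <- .lin_index(grid, site[1], site[2], site[3])
  sink_coef <- if (is.null(sink_rate)) numeric(N) else {
    if (any(sink_rate < 0, na.rm = TRUE)) stop("sink_rate must be >= 0")
    as.numeric(sink_rate) * V
  }
  idx3 <- array(seq_len(N), dim = shape)
  Ffaces <- list(flow$fx, flow$fy, flow$fz)

  ii <- jj <- xx <- vector("list", 16L); nt <- 0L
  diagv <- numeric(N)
  bnd_coef <- numeric(N)        # outward advective flux coefficient (Dirichlet faces)
  site_nb <- integer(0); site_out <- numeric(0); site_in <- numeric(0)

  for (ax in 1:3) {
    d <- grid$spacing[ax]
    area <- .face_area(grid, ax)
    n <- shape[ax]
    sl <- function(arr, r) {
      ix <- list(seq_len(shape[1]), seq_len(shape[2]), seq_len(shape[3]))
      ix[[ax]] <- r
      as.numeric(do.call(`[`, c(list(arr), ix)))
    }
    slf <- function(r) {         # face array slice
      fshape <- shape; fshape[ax] <- n + 1L
      ix <- list(seq_len(fshape[1]), seq_len(fshape[2]), seq_len(fshape[3]))
      ix[[ax]] <- r
      as.numeric(do.call(`[`, c(list(Ffaces[[ax]]), ix)))
    }
    if (n >= 2L) {
      I1 <- as.integer(sl(idx3, 1:(n - 1L)))
      I2 <- as.integer(sl(idx3, 2:n))
      F <- slf(2:n)
      Fp <- pmax(F, 0); Fm <- pmax(-F, 0)
      Dh <- area / d * .harmonic(sl(D_eff, 1:(n - 1L)), sl(D_eff, 2:n))
      diagv <- diagv + .tabsum(I1, Fp + Dh, N) + .tabsum(I2, Fm + Dh, N)
      nt <- nt + 1L
      ii[[nt]] <- c(I1, I2); jj[[nt]] <- c(I2, I1)
      xx[[nt]] <- c(-(Fm + Dh), -(Fp + Dh))
      # site face bookkeeping (outward from the held voxel)
      for (dir in 1:2) {
        from <- if (dir == 1L) I1 else I2
        to <- if (dir == 1L) I2 else I1
        w <- which(from == s_lin)
        if (length(w)) {
          Fo <- if (dir == 1L) Fp[w] else Fm[w]   # advective out of site
          Fi <- if (dir == 1L) Fm[w] else Fp[w]   # advective into site
          site_nb <- c(site_nb, to[w])
          site_out <- c(site_out, Fo + Dh[w])
          site_in <- c(site_in, Fi + Dh[w])
        }
      }
    }
    # outer box faces: only Dirichlet-pressure faces carry flux (no-flux
    # faces have F = 0); outflow removes mass at the upwind cell value,
    # inflow carries zero exterior concentration
    Ilow <- as.integer(sl(idx3, 1L))
    Ihigh <- as.integer(sl(idx3, n))
    out_low <- pmax(-slf(1L), 0)
    out_high <- pmax(slf(n + 1L), 0)
    diagv <- diagv + .tabsum(Ilow, out_low, N) + .tabsum(Ihigh, out_high, N)
    bnd_coef <- bnd_coef + .tabsum(Ilow, out_low, N) + .tabsum(Ihigh, out_high, N)
  }

  # backward-Euler system: (phiV/dt + L) c^{n+1} = phiV/dt c^n, with the
  # site row replaced by the (scaled) identity holding c_site = 1
  nt <- nt + 1L
  ii[[nt]] <- seq_len(N); jj[[nt]] <- seq_len(N)
  xx[[nt]] <- diagv + sink_coef + phiV / dt
  I <- unlist(ii[seq_len(nt)]); J <- unlist(jj[seq_len(nt)])
  X <- unlist(xx[seq_len(nt)])
  keep <- I != s_lin
  I <- c(I[keep], s_lin); J <- c(J[keep], s_lin)
  X <- c(X[keep], phiV[s_lin] / dt)
  M <- Matrix::sparseMatrix(i = I, j = J, x = X, dims = c(N, N))
  structure(list(lu = Matrix::lu(M), N = N, shape = shape, dt = dt,
                 phiV = phiV, site = s_lin, site_scale = phiV[s_lin] / dt,
                 site_nb = site_nb, site_out = site_out, site_in = site_in,
                 bnd_coef = bnd_coef, sink_coef = sink_coef),
            class = "transport_operator")
}

#' Advance the tracer field by one implicit time step
#'
#' @param op a [transport_operator()].
#' @param c_arr 3-D normalized concentration array.
#' @return 3-D array after one step of length `op$dt` (site held at 1).
#' @export
step_transport <- function(op, c_arr) {
  b <- op$phiV / op$dt * as.numeric(c_arr)
  b[op$site] <- op$site_scale
  array(as.numeric(Matrix::solve(op$lu, b)), dim = op$shape)
}

# mass audit terms evaluated at the post-step field; outflux covers cut-end
# advection plus drainage with absorbed fluid (lymph/capillary reabsorption)
.audit_terms <- function(op, c_new) {
  cs <- c_new[op$site]
  cv <- as.numeric(c_new)
  influx <- sum(op$site_out * cs - op$site_in * cv[op$site_nb])
  outflux <- sum(op$bnd_coef * cv) - op$bnd_coef[op$site] * cs +
    sum(op$sink_coef * cv) - op$sink_coef[op$site] * cs
  c(influx = influx, outflux = outflux)
}

#' Run a full infusion simulation
#'
#' Integrates tracer transport on the frozen flow field from `c = 0`
#' everywhere (except the infusion voxel, held at normalized concentration
#' 1 throughout) up to the protocol duration, recording the field at the
#' requested output times and a per-step discrete mass audit:
#' `d(total phi c)/dt` over the free voxels must equal influx from the held
#' voxel minus boundary outflux.
#'
#' @param maps a [ced_maps].
#' @param params a [tissue_params].
#' @param flow a `flow_field` from [solve_flow()] (same maps/protocol).
#' @param protocol an [infusion_protocol].
#' @param dt time step \[s\].
#' @return An object of class `tracer_field`: `times`, list `c_norm` of 3-D
#'   arrays (one per output time), `mass` data.frame (time, tracer mass
#'   \[m^3 of pore volume at infusate concentration\], influx, outflux,
#'   per-step relative mismatch), `site`, `dt`.
#' @export
run_infusion <- function(maps, params, flow, protocol, dt = 1) {
  stopifnot(inherits(maps, "ced_maps"), inherits(protocol, "infusion_protocol"))
  .check_site(protocol, maps$labels)
  grid <- maps$grid
  D_eff <- effective_diffusivity(maps$phi, maps$labels, params)
  sink <- NULL
  if (!is.null(flow$sources) && !is.null(flow$pressure)) {
    # fluid drainage pathways carry tracer out at local pore concentration:
    # lymphatic uptake and net capillary reabsorption (Starling reversed
    # where CED pressurizes above p_eff); filtration (tracer-free fluid in)
    # enters only through the face fluxes as dilution
    src <- flow$sources
    p <- flow$pressure
    vas <- (src$a - src$lymph * params$p_L) - (src$b - src$lymph) * p
    ly <- src$lymph * (p - params$p_L)
    sink <- pmax(-vas, 0) + pmax(ly, 0)
  }
  op <- transport_operator(flow, D_eff, maps$phi, grid, protocol$site, dt,
                           sink_rate = sink)
  c_arr <- array(0, dim = grid$shape)
  c_arr[op$site] <- 1
  out_times <- protocol$output_times[protocol$output_times <= protocol$duration]
  nsteps <- ceiling(protocol$duration / dt)
  snaps <- list(); snap_times <- numeric(0)
  if (protocol$duration == 0 || nsteps == 0L) {
    return(structure(list(times = 0, c_norm = list(c_arr),
                          mass = data.frame(time = numeric(0), mass = numeric(0),
                                            influx = numeric(0), outflux = numeric(0),
                                            mismatch_rel = numeric(0)),
                          site = protocol$site, dt = dt),
                     class = "tracer_field"))
  }
  free <- setdiff(seq_len(op$N), op$site)
  mass_prev <- sum(op$phiV[free] * as.numeric(c_arr)[free])
  rec <- matrix(0, nsteps, 5L,
                dimnames = list(NULL, c("time", "mass", "influx", "outflux",
                                        "mismatch_rel")))
  next_out <- 1L
  for (s in seq_len(nsteps)) {
    t_now <- s * dt
    c_arr <- step_transport(op, c_arr)
    m <- sum(op$phiV[free] * as.numeric(c_arr)[free])
    au <- .audit_terms(op, c_arr)
    dM <- m - mass_prev
    expected <- dt * (au["influx"] - au["outflux"])
    mism <- abs(dM - expected) /
      max(abs(expected), abs(dM), dt * au["influx"], .Machine$double.eps)
    rec[s, ] <- c(t_now, m, au["influx"], au["outflux"], mism)
    mass_prev <- m
    while (next_out <= length(out_times) &&
           t_now >= out_times[next_out] - dt / 2) {
      snaps[[length(snaps) + 1L]] <- c_arr
      snap_times <- c(snap_times, out_times[next_out])
      next_out <- next_out + 1L
    }
  }
  if (next_out <= length(out_times)) {   # duration not a multiple of dt
    snaps[[length(snaps) + 1L]] <- c_arr
    snap_times <- c(snap_times, out_times[next_out])
  }
  structure(list(times = snap_times, c_norm = snaps,
                 mass = as.data.frame(rec), site = protocol$site, dt = dt),
            class = "tracer_field")
}
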