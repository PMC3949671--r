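# Steady interstitial pressure / velocity solver.
#
# Cell-centered finite volumes on the voxel grid:
#   div(-K grad p) = a - b p + ced      (all terms per unit tissue volume)
# with harmonic-mean face conductances, zero-pressure Dirichlet at cut-end
# box faces (ghost half-cell), no-flux on the remaining outer surface.  The
# affine pressure-dependent sources go on the diagonal, so one SPD solve
# gives the exact steady state.  An optional embedded Dirichlet boundary
# (mask + level set, Shortley-Weller fractional face distances) supports
# the closed-form verification oracles on non-box domains.

.face_area <- function(grid, axis) grid$voxel_volume / grid$spacing[axis]

.harmonic <- function(a, b) {
  s <- a + b
  out <- numeric(length(s))
  ok <- s > 0
  out[ok] <- 2 * a[ok] * b[ok] / s[ok]
  out
}

#' Assemble the sparse pressure system
#'
#' @param K 3-D hydraulic conductivity array \[m^2/(Pa s)\], all > 0.
#' @param sources a [source_field] (affine coefficients `a`, `b`, CED term).
#' @param bcs boundary table from [classify_boundary()] (ignored in
#'   embedded mode).
#' @param grid a [voxel_grid].
#' @param mask optional logical 3-D array of solved cells (embedded mode);
#'   faces crossing the mask edge become Dirichlet faces at the zero level
#'   set of `levelset`.
#' @param levelset 3-D array, negative inside the solved domain; required
#'   with `mask`.
#' @param dirichlet_fun optional vectorized `function(x, y, z)` giving the
#'   boundary pressure at level-set crossing points \[Pa\]; default 0.
#' @param crossing_fun optional exact boundary geometry for embedded mode:
#'   vectorized `function(px, py, pz, ax, sgn)` returning the distance \[m\]
#'   from a cell centre to the boundary along `sgn`*axis `ax`.  Falls back
#'   to linear interpolation of `levelset` (first-order for curved
#'   boundaries) when absent.
#' @return list of class `pressure_system`: symmetric sparse matrix `A`
#'   \[m^3/(Pa s)\], right-hand side `rhs` \[m^3/s\], `mask`, `grid`.
#' @export
assemble_pressure_system <- function(K, sources, bcs, grid, mask = NULL,
                                     levelset = NULL, dirichlet_fun = NULL,
                                     crossing_fun = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (any(!is.finite(K)) || any(K <= 0)) stop("K must be positive and finite")
  shape <- grid$shape
  N <- prod(shape)
  embedded <- !is.null(mask)
  if (embedded && is.null(levelset)) stop("embedded mode requires a levelset")
  if (!embedded) mask <- array(TRUE, dim = shape)
  ridx <- integer(N)
  sel <- which(mask)
  nun <- length(sel)
  ridx[sel] <- seq_len(nun)
  idx3 <- array(seq_len(N), dim = shape)

  V <- grid$voxel_volume
  ii <- jj <- vector("list", 8L); xx <- vector("list", 8L); nt <- 0L
  diag_extra <- numeric(nun)
  rhs <- (as.numeric(sources$a)[sel] + as.numeric(sources$ced)[sel]) * V
  diag_extra <- diag_extra + as.numeric(sources$b)[sel] * V

  coords <- lapply(1:3, function(a) axis_coords(grid, a))

  for (ax in 1:3) {
    d <- grid$spacing[ax]
    area <- .face_area(grid, ax)
    n <- shape[ax]
    if (n < 2L) next
    sl <- function(r) {
      ix <- list(seq_len(shape[1]), seq_len(shape[2]), seq_len(shape[3]))
      ix[[ax]] <- r
      do.call(`[`, c(list(idx3), ix))
    }
    I1 <- as.integer(sl(1:(n - 1L)))
    I2 <- as.integer(sl(2:n))
    in1 <- mask[I1]; in2 <- mask[I2]
    both <- in1 & in2
    if (any(both)) {
      Tcond <- area / d * .harmonic(K[I1[both]], K[I2[both]])
      r1 <- ridx[I1[both]]; r2 <- ridx[I2[both]]
      nt <- nt + 1L
      ii[[nt]] <- c(r1, r2, r1, r2)
      jj[[nt]] <- c(r1, r2, r2, r1)
      xx[[nt]] <- c(Tcond, Tcond, -Tcond, -Tcond)
    }
    if (embedded) {
      # faces from an inside cell to an excluded neighbor: Dirichlet at the
      # level-set crossing, fractional distance theta*d (Shortley-Weller)
      for (dir in 1:2) {
        Iin <- if (dir == 1L) I1[in1 & !in2] else I2[in2 & !in1]
        Iout <- if (dir == 1L) I2[in1 & !in2] else I1[in2 & !in1]
        if (!length(Iin)) next
        sgn <- if (dir == 1L) 1 else -1
        sub_in <- arrayInd(Iin, shape)
        px <- coords[[1]][sub_in[, 1]]
        py <- coords[[2]][sub_in[, 2]]
        pz <- coords[[3]][sub_in[, 3]]
        if (!is.null(crossing_fun)) {
          theta <- crossing_fun(px, py, pz, ax, sgn) / d
        } else {
          ls_in <- levelset[Iin]; ls_out <- levelset[Iout]
          theta <- ls_in / (ls_in - ls_out)
        }
        theta <- pmin(pmax(theta, 1e-3), 1)
        Tg <- area * K[Iin] / (theta * d)
        r <- ridx[Iin]
        diag_extra <- diag_extra + .tabsum(r, Tg, nun)
        if (!is.null(dirichlet_fun)) {
          pc <- list(px, py, pz)
          pc[[ax]] <- pc[[ax]] + sgn * theta * d
          g <- dirichlet_fun(pc[[1]], pc[[2]], pc[[3]])
          rhs <- rhs + .tabsum(r, Tg * g, nun)
        }
      }
    }
  }

  ndir <- 0L
  if (!embedded && !is.null(bcs)) {
    dir_rows <- bcs[bcs$bc == "DIRICHLET_P0", , drop = FALSE]
    ndir <- nrow(dir_rows)
    if (ndir > 0L) {
      ax <- match(substr(dir_rows$side, 1, 1), c("x", "y", "z"))
      d <- grid$spacing[ax]
      area <- V / d
      Tg <- area * K[dir_rows$cell] / (d / 2)
      diag_extra <- diag_extra + .tabsum(ridx[dir_rows$cell], Tg, nun)
    }
  }

  if (!embedded && ndir == 0L && all(diag_extra == 0)) {
    stop(errorCondition(
      "singular pressure system: no Dirichlet faces and no pressure-dependent sources",
      class = "cedsim_singular_error"))
  }

  nt <- nt + 1L
  ii[[nt]] <- seq_len(nun); jj[[nt]] <- seq_len(nun); xx[[nt]] <- diag_extra
  A <- Matrix::sparseMatrix(i = unlist(ii[seq_len(nt)]),
                            j = unlist(jj[seq_len(nt)]),
                            x = unlist(xx[seq_len(nt)]),
                            dims = c(nun, nun))
  structure(list(A = Matrix::forceSymmetric(A), rhs = rhs, mask = mask,
                 grid = grid, embedded = embedded),
            class = "pressure_system")
}

# sum values v into bins r (1..n); dense accumulator
.tabsum <- function(r, v, n) {
  out <- numeric(n)
  agg <- rowsum(v, r)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Solve the assembled pressure system
#'
#' Direct sparse Cholesky (CHOLMOD) for small or plate-like systems,
#' Jacobi-preconditioned conjugate gradients for large 3-D blocks (where
#' fill-in makes the direct factorization expensive).  Both paths are
#' deterministic for fixed inputs; the relative residual is checked against
#' `tol` and non-convergence raises an error carrying the residual history.
#'
#' @param system a `pressure_system` from [assemble_pressure_system()].
#' @param tol maximum acceptable relative residual.
#' @param method `"auto"`, `"direct"` or `"cg"`.
#' @param maxiter CG iteration cap.
#' @return list: `pressure` 3-D array \[Pa\] (NA outside the solved mask in
#'   embedded mode), `residual_norm`, `method`, `iterations`.
#' @export
solve_pressure <- function(system, tol = 1e-8,
                           method = c("auto", "direct", "cg"),
                           maxiter = 20000L) {
  method <- match.arg(method)
  A <- system$A; b <- system$rhs
  iters <- 0L
  if (method == "auto") {
    # direct factorization fills badly on large near-cubic 3-D domains;
    # thin (few-slice) grids factor cheaply
    big3d <- nrow(A) > 60000L && min(system$grid$shape) > 16L
    method <- if (big3d) "cg" else "direct"
  }
  if (all(b == 0)) {
    x <- numeric(length(b)); res <- 0
  } else if (method == "direct") {
    ch <- Matrix::Cholesky(A, LDL = FALSE, perm = TRUE)
    x <- as.numeric(Matrix::solve(ch, b))
    res <- sqrt(sum((as.numeric(A %*% x) - b)^2)) / sqrt(sum(b^2))
  } else {
    d <- Matrix::diag(A)
    if (any(d <= 0)) stop("CG requires a positive diagonal")
    bnorm <- sqrt(sum(b^2))
    x <- numeric(length(b))
    r <- b
    z <- r / d
    p <- z
    rz <- sum(r * z)
    hist <- numeric(0)
    repeat {
      iters <- iters + 1L
      Ap <- as.numeric(A %*% p)
      alpha <- rz / sum(p * Ap)
      x <- x + alpha * p
      r <- r - alpha * Ap
      res <- sqrt(sum(r^2)) / bnorm
      hist <- c(hist, res)
      if (res <= tol * 0.1 || iters >= maxiter) break
      z <- r / d
      rz_new <- sum(r * z)
      beta <- rz_new / rz
      rz <- rz_new
      p <- z + beta * p
    }
    if (res > tol) {
      cond <- errorCondition(
        sprintf("CG did not converge in %d iterations (residual %.3g)",
                iters, res),
        class = "cedsim_solver_error")
      cond$residual_history <- hist
      stop(cond)
    }
  }
  if (!is.finite(res) || res > tol) {
    stop(errorCondition(
      sprintf("pressure solve did not reach tolerance: residual %.3g > %.3g",
              res, tol),
      class = "cedsim_solver_error"))
  }
  p <- array(NA_real_, dim = system$grid$shape)
  p[system$mask] <- x
  list(pressure = p, residual_norm = res, method = method, iterations = iters)
}

#' Face fluxes, Darcy and interstitial velocities from a solved pressure
#'
#' Face volumetric fluxes \[m^3/s\] use the same harmonic-mean conductances
#' as the assembly (discrete flux consistency); boundary Dirichlet faces use
#' the ghost half-cell conductance.  Cell-centred Darcy velocity components
#' are the mean of the two face velocities per axis; the interstitial (pore)
#' velocity divides by local porosity (an effective porosity of 1 is used in
#' exterior voxels, where the sentinel NA lives).
#'
#' @param p 3-D pressure array \[Pa\].
#' @param K 3-D conductivity array.
#' @param phi 3-D porosity array (NA allowed in exterior).
#' @param grid a [voxel_grid].
#' @param bcs boundary table from [classify_boundary()].
#' @param lmap a [label_map].
#' @return list: face flux arrays `fx`,`fy`,`fz` (dims `(n+1)` along own
#'   axis, positive along +axis), Darcy velocity arrays `qx`,`qy`,`qz` and
#'   magnitude `speed` \[m/s\], interstitial velocity magnitude `speed_ifv`,
#'   `boundary_outflux` \[m^3/s\].
#' @export
compute_velocity <- function(p, K, phi, grid, bcs, lmap) {
  shape <- grid$shape
  lab <- lmap$labels
  tis <- lab != LABEL_EXTERIOR
  if (any(tis & (!is.na(phi)) & phi <= 0)) {
    stop("porosity must be > 0 in tissue voxels")
  }
  phie <- phi
  phie[!tis | is.na(phi)] <- 1
  idx3 <- array(seq_len(prod(shape)), dim = shape)
  F <- list()
  for (ax in 1:3) {
    d <- grid$spacing[ax]
    area <- .face_area(grid, ax)
    n <- shape[ax]
    fdim <- shape; fdim[ax] <- n + 1L
    f <- array(0, dim = fdim)
    if (n >= 2L) {
      sl <- function(arr, r) {
        ix <- list(seq_len(shape[1]), seq_len(shape[2]), seq_len(shape[3]))
        ix[[ax]] <- r
        do.call(`[`, c(list(arr), ix, list(drop = FALSE)))
      }
      K1 <- sl(K, 1:(n - 1L)); K2 <- sl(K, 2:n)
      hm <- array(.harmonic(as.numeric(K1), as.numeric(K2)), dim = dim(K1))
      flux <- area / d * hm * (sl(p, 1:(n - 1L)) - sl(p, 2:n))
      ix <- list(seq_len(fdim[1]), seq_len(fdim[2]), seq_len(fdim[3]))
      ix[[ax]] <- 2:n
      f <- do.call(`[<-`, c(list(f), ix, list(flux)))
    }
    F[[ax]] <- f
  }
  boundary_outflux <- 0
  if (!is.null(bcs)) {
    dir_rows <- bcs[bcs$bc == "DIRICHLET_P0", , drop = FALSE]
    if (nrow(dir_rows) > 0L) {
      for (r in seq_len(nrow(dir_rows))) {
        side <- dir_rows$side[r]
        ax <- match(substr(side, 1, 1), c("x", "y", "z"))
        low <- substr(side, 2, 2) == "-"
        d <- grid$spacing[ax]
        area <- .face_area(grid, ax)
        cell <- dir_rows$cell[r]
        Tg <- area * K[cell] / (d / 2)
        fl <- Tg * p[cell]                 # outward volumetric flux
        boundary_outflux <- boundary_outflux + fl
        sub <- c(dir_rows$ix[r], dir_rows$iy[r], dir_rows$iz[r])
        fidx <- sub
        fidx[ax] <- if (low) 1L else shape[ax] + 1L
        F[[ax]][fidx[1], fidx[2], fidx[3]] <- if (low) -fl else fl
      }
    }
  }
  q <- vector("list", 3L)
  for (ax in 1:3) {
    area <- .face_area(grid, ax)
    n <- shape[ax]
    ixl <- list(seq_len(shape[1]), seq_len(shape[2]), seq_len(shape[3]))
    lo <- ixl; lo[[ax]] <- 1:n
    hi <- ixl; hi[[ax]] <- 2:(n + 1L)
    q[[ax]] <- 0.5 * (do.call(`[`, c(list(F[[ax]]), lo, list(drop = FALSE))) +
                      do.call(`[`, c(list(F[[ax]]), hi, list(drop = FALSE)))) / area
    q[[ax]] <- array(q[[ax]], dim = shape)
  }
  speed <- sqrt(q[[1]]^2 + q[[2]]^2 + q[[3]]^2)
  list(fx = F[[1]], fy = F[[2]], fz = F[[3]],
       qx = q[[1]], qy = q[[2]], qz = q[[3]],
       speed = speed, speed_ifv = speed / phie,
       boundary_outflux = boundary_outflux)
}

#' Solve the full steady flow problem on a set of maps
#'
#' Pipeline convenience: normalized Ktrans, conductivity, sources, boundary
#' classification, assembly, solve, velocity reconstruction and the global
#' mass-balance audit in one call.
#'
#' @param maps a [ced_maps].
#' @param params a [tissue_params].
#' @param protocol optional [infusion_protocol] (adds the CED point source).
#' @param gamma conductivity exponent override.
#' @param tol solver tolerance (relative residual).
#' @return An object of class `flow_field`: `pressure` \[Pa\], face fluxes,
#'   Darcy velocity components and `speed` \[m/s\], interstitial speed
#'   `speed_ifv`, `residual_norm`, `mass_balance_rel`, `peak_ifp_tumor`,
#'   `peak_speed`, plus the `K`, `sources`, `bcs` used.
#' @export
solve_flow <- function(maps, params, protocol = NULL, gamma = params$gamma,
                       tol = 1e-8) {
  stopifnot(inherits(maps, "ced_maps"))
  lmap <- maps$labels; grid <- maps$grid
  kn <- normalize_ktrans(maps$ktrans, lmap)
  K <- conductivity_map(maps$phi, lmap, params, gamma = gamma)
  src <- source_field(kn$ktrans_norm, lmap, params, protocol = protocol,
                      grid = grid)
  bcs <- classify_boundary(grid, lmap)
  sys <- assemble_pressure_system(K, src, bcs, grid)
  sol <- solve_pressure(sys, tol = tol)
  p <- sol$pressure
  vel <- compute_velocity(p, K, maps$phi, grid, bcs, lmap)
  V <- grid$voxel_volume
  total_source <- sum((src$a - src$b * p) * V) + sum(src$ced) * V
  denom <- max(abs(total_source), sum(abs(src$a) * V), .Machine$double.eps)
  mb <- abs(total_source - vel$boundary_outflux) / denom
  tum <- lmap$labels == LABEL_TUMOR
  structure(c(list(pressure = p,
                   residual_norm = sol$residual_norm,
                   mass_balance_rel = mb,
                   total_source = total_source,
                   peak_ifp_tumor = if (any(tum)) max(p[tum]) else NA_real_,
                   peak_speed = max(vel$speed),
                   ktrans_norm = kn$ktrans_norm,
                   K = K, sources = src, bcs = bcs, grid = grid),
              vel),
            class = "flow_field")
}

#' Mean Darcy speed at the skin interface vs peak interior speed
#'
#' Diagnostic for the skin-impermeability treatment: the mean velocity
#' magnitude over tissue voxels adjacent to exterior voxels, together with
#' the peak interior tissue speed.
#'
#' @param flow a `flow_field` from [solve_flow()].
#' @param lmap a [label_map].
#' @return list `mean_skin_speed`, `peak_tissue_speed`, `ratio`.
#' @export
skin_interface_speed <- function(flow, lmap) {
  lab <- lmap$labels
  shape <- dim(lab)
  tis <- lab != LABEL_EXTERIOR
  near_ext <- array(FALSE, dim = shape)
  shift <- function(arr, ax, by) {
    n <- shape[ax]
    out <- array(FALSE, dim = shape)
    src <- list(seq_len(shape[1]), seq_len(shape[2]), seq_len(shape[3]))
    dst <- src
    if (by > 0) { dst[[ax]] <- 2:n; src[[ax]] <- 1:(n - 1L) }
    else { dst[[ax]] <- 1:(n - 1L); src[[ax]] <- 2:n }
    out <- do.call(`[<-`, c(list(out), dst,
                            list(do.call(`[`, c(list(arr), src)))))
    out
  }
  ext <- !tis
  for (ax in 1:3) {
    near_ext <- near_ext | shift(ext, ax, 1L) | shift(ext, ax, -1L)
  }
  skin <- tis & near_ext
  interior <- tis & !near_ext
  ms <- if (any(skin)) mean(flow$speed[skin]) else 0
  ps <- if (any(interior)) max(flow$speed[interior]) else max(flow$speed[tis])
  list(mean_skin_speed = ms, peak_tissue_speed = ps,
       ratio = ms / max(ps, .Machine$double.eps))
}
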