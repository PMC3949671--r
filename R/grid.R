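# Voxel grid, tissue labels, boundary classification and map I/O.
#
# All quantities inside the package are SI (m, Pa, s).  External files may
# use imaging conventions (mm spacing in NIfTI headers, Ktrans in 1/min);
# conversion happens exactly once, at load time.

#' Tissue label codes
#'
#' Integer codes used in label volumes: `0` exterior (outside the animal),
#' `1` host tissue, `2` tumor.
#' @export
LABEL_EXTERIOR <- 0L
#' @rdname LABEL_EXTERIOR
#' @export
LABEL_HOST <- 1L
#' @rdname LABEL_EXTERIOR
#' @export
LABEL_TUMOR <- 2L

.box_sides <- c("x-", "x+", "y-", "y+", "z-", "z+")

#' Define a regular voxel grid
#'
#' The spatial scaffold every field lives on: a box of `shape` voxels with
#' per-axis `spacing` in metres.
#'
#' @param shape integer triple (nx, ny, nz).
#' @param spacing length triple, metres per voxel along each axis.
#' @param origin coordinate of the centre of voxel (1,1,1), metres.
#' @return An object of class `voxel_grid` with fields `shape`, `spacing`,
#'   `voxel_volume` (m^3), `origin`, and `extent` (physical box size, m).
#' @export
voxel_grid <- function(shape, spacing, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  stopifnot(length(shape) == 3L, length(spacing) == 3L, length(origin) == 3L)
  if (any(shape < 1L)) stop("grid shape must be positive")
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("all grid spacings must be positive")
  }
  structure(list(
    shape = shape,
    spacing = spacing,
    voxel_volume = prod(spacing),
    origin = as.numeric(origin),
    extent = shape * spacing
  ), class = "voxel_grid")
}

#' @method print voxel_grid
#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d voxels, spacing %s mm, %.3g mm^3/voxel\n",
              x$shape[1], x$shape[2], x$shape[3],
              paste(signif(x$spacing * 1e3, 4), collapse = " x "),
              x$voxel_volume * 1e9))
  invisible(x)
}

#' Default imaging grid
#'
#' A 20 x 10 x 9 mm^3 box at MRI resolution 0.104 x 0.104 x 1 mm
#' (192 x 96 x 9 voxels), the domain used for the hind-limb simulations.
#' `scale` coarsens the in-plane resolution (e.g. `scale = 2` gives
#' 96 x 48 x 9 voxels at 0.208 mm) while keeping the physical extent.
#'
#' @param scale integer in-plane coarsening factor.
#' @return A [voxel_grid].
#' @export
default_grid <- function(scale = 1L) {
  scale <- as.integer(scale)
  stopifnot(scale >= 1L)
  voxel_grid(shape = c(192L %/% scale, 96L %/% scale, 9L),
             spacing = c(0.104e-3 * scale, 0.104e-3 * scale, 1e-3))
}

#' Voxel centre coordinates along one axis
#' @param grid a [voxel_grid].
#' @param axis 1, 2 or 3.
#' @return numeric vector of centre coordinates [m].
#' @export
axis_coords <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$shape[axis]) - 1) * grid$spacing[axis]
}

# linear index of voxel (i,j,k), column-major like R arrays
.lin_index <- function(grid, i, j, k) {
  nx <- grid$shape[1]; ny <- grid$shape[2]
  as.integer(i + (j - 1L) * nx + (k - 1L) * as.double(nx) * ny)
}

#' Tissue label map
#'
#' Wraps an integer label volume together with the set of box sides that are
#' open tissue cross-sections ("cut ends").  Cut ends are explicit metadata:
#' they stem from the limited imaging field of view, not from anatomy, so
#' they are never inferred.
#'
#' @param labels integer 3-D array with values in
#'   \{[LABEL_EXTERIOR], [LABEL_HOST], [LABEL_TUMOR]\}.
#' @param cut_ends character vector, subset of
#'   `c("x-","x+","y-","y+","z-","z+")`; defaults to the two faces
#'   transverse to the limb axis.
#' @return An object of class `label_map`.
#' @export
label_map <- function(labels, cut_ends = c("x-", "x+")) {
  if (length(dim(labels)) != 3L) stop("labels must be a 3-D array")
  labels <- array(as.integer(labels), dim = dim(labels))
  bad <- !(labels %in% c(LABEL_EXTERIOR, LABEL_HOST, LABEL_TUMOR))
  if (any(bad)) {
    stop(errorCondition(
      sprintf("label volume contains %d voxels with codes outside {0,1,2}",
              sum(bad)),
      class = "cedsim_label_error"))
  }
  if (!all(cut_ends %in% .box_sides)) stop("unknown cut-end face name")
  structure(list(labels = labels, cut_ends = unique(cut_ends)),
            class = "label_map")
}

#' @method print label_map
#' @export
print.label_map <- function(x, ...) {
  tb <- table(factor(x$labels, levels = 0:2,
                     labels = c("exterior", "host", "tumor")))
  cat(sprintf("<label_map> %s voxels: %s; cut ends: %s\n",
              paste(dim(x$labels), collapse = "x"),
              paste(names(tb), as.integer(tb), sep = "=", collapse = ", "),
              paste(x$cut_ends, collapse = ", ")))
  invisible(x)
}

# For each of the 6 box sides: the (nx,ny,nz)-consistent index slab of
# adjacent cells and the axis/orientation.
.side_info <- function(side, shape) {
  ax <- match(substr(side, 1, 1), c("x", "y", "z"))
  lo <- substr(side, 2, 2) == "-"
  idx <- if (lo) 1L else shape[ax]
  list(axis = ax, low = lo, layer = idx)
}

#' Classify outer box faces into pressure boundary conditions
#'
#' Every face of the outer box surface is classified exhaustively and
#' exclusively: a face lying on a cut-end side of the box and adjacent to a
#' non-exterior voxel is an open tissue cross-section and gets zero-pressure
#' Dirichlet; every other outer face is an impermeable wall (no flux).
#'
#' @param grid a [voxel_grid].
#' @param lmap a [label_map].
#' @return data.frame with one row per outer face: `side`, adjacent-cell
#'   indices `ix`,`iy`,`iz`, linear cell index `cell`, and `bc`
#'   (`"DIRICHLET_P0"` or `"NOFLUX"`).
#' @export
classify_boundary <- function(grid, lmap) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(lmap, "label_map"))
  if (!all(dim(lmap$labels) == grid$shape)) {
    stop(errorCondition("label volume shape does not match grid",
                        class = "cedsim_shape_error"))
  }
  out <- vector("list", 6L)
  for (s in seq_along(.box_sides)) {
    side <- .box_sides[s]
    si <- .side_info(side, grid$shape)
    other <- setdiff(1:3, si$axis)
    n1 <- grid$shape[other[1]]; n2 <- grid$shape[other[2]]
    u <- rep(seq_len(n1), times = n2)
    v <- rep(seq_len(n2), each = n1)
    ijk <- matrix(0L, n1 * n2, 3L)
    ijk[, si$axis] <- si$layer
    ijk[, other[1]] <- u
    ijk[, other[2]] <- v
    cell <- .lin_index(grid, ijk[, 1], ijk[, 2], ijk[, 3])
    tissue <- lmap$labels[cell] != LABEL_EXTERIOR
    bc <- ifelse(side %in% lmap$cut_ends & tissue, "DIRICHLET_P0", "NOFLUX")
    out[[s]] <- data.frame(side = side, ix = ijk[, 1], iy = ijk[, 2],
                           iz = ijk[, 3], cell = cell, bc = bc,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Bundle grid, labels and parameter maps
#'
#' @param grid a [voxel_grid].
#' @param lmap a [label_map].
#' @param ktrans 3-D array, vascular rate-transfer constant [1/s];
#'   0 in exterior voxels.
#' @param phi 3-D array, porosity (extracellular volume fraction) in (0,1);
#'   `NA` sentinel in exterior voxels.
#' @return An object of class `ced_maps`.
#' @export
ced_maps <- function(grid, lmap, ktrans, phi) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(lmap, "label_map"))
  for (nm in c("ktrans", "phi")) {
    v <- get(nm)
    if (!all(dim(v) == grid$shape)) {
      stop(errorCondition(sprintf("volume '%s' shape does not match grid", nm),
                          class = "cedsim_shape_error"))
    }
  }
  structure(list(grid = grid, labels = lmap, ktrans = ktrans, phi = phi),
            class = "ced_maps")
}

#' Save label / Ktrans / porosity maps as NIfTI volumes
#'
#' Writes `<prefix>_labels.nii.gz`, `<prefix>_ktrans.nii.gz`,
#' `<prefix>_phi.nii.gz` (spacing in mm in the headers, the NIfTI
#' convention) plus a JSON sidecar `<prefix>_meta.json` recording units
#' (Ktrans in 1/s) and the cut-end faces.
#'
#' @param maps a [ced_maps] object.
#' @param prefix path prefix for the output files.
#' @return invisibly, the vector of files written.
#' @export
save_maps <- function(maps, prefix) {
  stopifnot(inherits(maps, "ced_maps"))
  pd <- maps$grid$spacing * 1e3          # m -> mm for the header
  files <- c(labels = paste0(prefix, "_labels.nii.gz"),
             ktrans = paste0(prefix, "_ktrans.nii.gz"),
             phi = paste0(prefix, "_phi.nii.gz"),
             meta = paste0(prefix, "_meta.json"))
  wr <- function(arr, file, dt) {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- pd
    RNifti::writeNifti(img, file, datatype = dt)
  }
  wr(maps$labels$labels, files["labels"], "int32")
  wr(maps$ktrans, files["ktrans"], "double")
  wr(maps$phi, files["phi"], "double")
  meta <- list(ktrans_units = "1/s",
               cut_ends = maps$labels$cut_ends,
               origin_m = maps$grid$origin,
               # exact spacing; NIfTI headers hold pixdim in float32 only
               spacing_m = maps$grid$spacing)
  jsonlite::write_json(meta, files["meta"], auto_unbox = TRUE, digits = NA)
  invisible(files)
}

#' Load label / Ktrans / porosity maps written by [save_maps()]
#'
#' Volumes must agree in shape and spacing; any disagreement raises a
#' structured error naming the offending volume and axis.  Porosity values
#' outside (0,1) in tissue voxels are clipped into \[0.01, 0.99\] with a
#' warning reporting the count (never silently).  If the sidecar declares
#' `ktrans_units: "1/min"` (the common DCE convention) the map is converted
#' to 1/s here, the package's single unit-conversion point.
#'
#' @param prefix path prefix used at save time.
#' @return A [ced_maps] object.
#' @export
load_maps <- function(prefix) {
  files <- c(labels = paste0(prefix, "_labels.nii.gz"),
             ktrans = paste0(prefix, "_ktrans.nii.gz"),
             phi = paste0(prefix, "_phi.nii.gz"),
             meta = paste0(prefix, "_meta.json"))
  for (f in files[1:3]) {
    if (!file.exists(f)) {
      stop(errorCondition(sprintf("missing volume file '%s'", f),
                          class = "cedsim_io_error"))
    }
  }
  imgs <- lapply(files[1:3], RNifti::readNifti)
  shp <- lapply(imgs, dim)
  sp <- lapply(imgs, function(im) RNifti::pixdim(im)[1:3])
  ref <- names(imgs)[1]
  for (nm in names(imgs)[-1]) {
    if (!identical(shp[[nm]], shp[[ref]])) {
      bad_ax <- which(shp[[nm]] != shp[[ref]])[1]
      stop(errorCondition(
        sprintf("volume '%s' shape mismatch on axis %s (%d vs %d)",
                nm, c("x", "y", "z")[bad_ax], shp[[nm]][bad_ax],
                shp[[ref]][bad_ax]),
        class = "cedsim_shape_error"))
    }
    if (any(abs(sp[[nm]] - sp[[ref]]) > 1e-9)) {
      bad_ax <- which(abs(sp[[nm]] - sp[[ref]]) > 1e-9)[1]
      stop(errorCondition(
        sprintf("volume '%s' spacing mismatch on axis %s",
                nm, c("x", "y", "z")[bad_ax]),
        class = "cedsim_shape_error"))
    }
  }
  meta <- if (file.exists(files["meta"])) {
    jsonlite::read_json(files["meta"], simplifyVector = TRUE)
  } else list()
  origin <- if (!is.null(meta$origin_m)) as.numeric(meta$origin_m) else c(0, 0, 0)
  spacing <- if (!is.null(meta$spacing_m)) as.numeric(meta$spacing_m)
             else sp[[ref]] * 1e-3
  grid <- voxel_grid(shp[[ref]], spacing, origin = origin)
  cut_ends <- if (!is.null(meta$cut_ends)) meta$cut_ends else c("x-", "x+")
  lmap <- label_map(array(as.integer(imgs$labels), dim = grid$shape),
                    cut_ends = cut_ends)
  ktrans <- array(as.numeric(imgs$ktrans), dim = grid$shape)
  if (identical(meta$ktrans_units, "1/min")) ktrans <- ktrans / 60
  phi <- array(as.numeric(imgs$phi), dim = grid$shape)
  tissue <- lmap$labels != LABEL_EXTERIOR
  oob <- tissue & (!is.na(phi)) & (phi <= 0 | phi >= 1)
  if (any(oob)) {
    warning(sprintf("porosity outside (0,1) in %d voxels; clipped to [0.01, 0.99]",
                    sum(oob)))
    phi[oob] <- pmin(pmax(phi[oob], 0.01), 0.99)
  }
  ced_maps(grid, lmap, ktrans, phi)
}
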