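#' Volumetric grid with physical spacing
#'
#' The image carrier used throughout the package: a 3D array of scalars plus
#' per-axis voxel spacing and the world coordinate (mm) of the centre of the
#' first voxel. World coordinates follow `world = origin + (index - 1) *
#' spacing` with 1-based indices; axes are x (dim 1, right), y (dim 2,
#' anterior) and z (dim 3, superior), i.e. an axis-aligned RAS frame.
#'
#' @param data numeric 3D array.
#' @param spacing_mm numeric length-3, voxel size per axis in mm.
#' @param origin_mm numeric length-3, world position (mm) of voxel (1,1,1).
#' @return an object of class `vol_grid`.
#' @export
vol_grid <- function(data, spacing_mm, origin_mm = c(0, 0, 0)) {
  stopifnot(length(dim(data)) == 3L, length(spacing_mm) == 3L,
            all(spacing_mm > 0), length(origin_mm) == 3L)
  structure(list(data = data, spacing = as.numeric(spacing_mm),
                 origin = as.numeric(origin_mm)),
            class = "vol_grid")
}

#' Integer label map on a volumetric grid
#'
#' A [vol_grid()] whose voxels are integer labels 0 (background) to 8
#' (Couinaud segments S1–S8).
#'
#' @inheritParams vol_grid
#' @return an object of class `c("label_map", "vol_grid")`.
#' @export
label_map <- function(data, spacing_mm, origin_mm = c(0, 0, 0)) {
  v <- vol_grid(array(as.integer(round(data)), dim(data)), spacing_mm,
                origin_mm)
  if (any(v$data < 0L | v$data > 8L)) {
    stop("label map values must lie in 0..8")
  }
  class(v) <- c("label_map", "vol_grid")
  v
}

#' @export
print.vol_grid <- function(x, ...) {
  cat(sprintf("<%s> %s voxels @ %s mm, origin (%s) mm\n",
              class(x)[1], paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing, trim = TRUE), collapse = "x"),
              paste(format(x$origin, trim = TRUE), collapse = ", ")))
  invisible(x)
}

#' @export
dim.vol_grid <- function(x) dim(x$data)

#' Plot an axial slice of a volume
#'
#' Quick-look display of one z-slice; label maps use a discrete palette.
#'
#' @param x a [vol_grid()] or [label_map()].
#' @param z slice index (default: middle slice).
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.vol_grid <- function(x, z = NULL, ...) {
  z <- z %||% ((dim(x$data)[3] + 1L) %/% 2L)
  sl <- x$data[, , z]
  if (inherits(x, "label_map")) {
    cols <- c("black", "#8dd3c7", "#ffffb3", "#bebada", "#fb8072",
              "#80b1d3", "#fdb462", "#b3de69", "#fccde5")
    graphics::image(axis_coords_mm(x, 1), axis_coords_mm(x, 2), sl,
                    col = cols[sort(unique(as.integer(sl))) + 1L],
                    asp = 1, xlab = "x (mm)", ylab = "y (mm)", ...)
  } else {
    graphics::image(axis_coords_mm(x, 1), axis_coords_mm(x, 2), sl,
                    col = grDevices::gray.colors(128), asp = 1,
                    xlab = "x (mm)", ylab = "y (mm)", ...)
  }
  invisible(x)
}

#' Physical volume of one voxel in mm^3
#' @param vg a [vol_grid()].
#' @return scalar mm^3.
#' @export
voxel_volume_mm3 <- function(vg) prod(vg$spacing)

#' World coordinates (mm) of voxel centres
#'
#' @param vg a [vol_grid()].
#' @param idx integer matrix (n x 3) of 1-based voxel indices; if `NULL`,
#'   all voxels in array order.
#' @return n x 3 matrix of mm coordinates.
#' @export
voxel_coords_mm <- function(vg, idx = NULL) {
  if (is.null(idx)) {
    idx <- arrayInd(seq_along(vg$data), dim(vg$data))
  }
  sweep(sweep(idx - 1, 2, vg$spacing, `*`), 2, vg$origin, `+`)
}

#' Per-axis voxel-centre coordinates
#' @param vg a [vol_grid()].
#' @param axis 1, 2 or 3.
#' @return numeric vector of mm coordinates along that axis.
#' @export
axis_coords_mm <- function(vg, axis) {
  vg$origin[axis] + (seq_len(dim(vg$data)[axis]) - 1) * vg$spacing[axis]
}

#' Nearest voxel index for world coordinates
#' @param vg a [vol_grid()].
#' @param pts n x 3 matrix of mm coordinates.
#' @return n x 3 integer matrix of 1-based indices (unclamped).
#' @keywords internal
world_to_index <- function(vg, pts) {
  pts <- matrix(pts, ncol = 3)
  round(sweep(sweep(pts, 2, vg$origin, `-`), 2, vg$spacing, `/`)) + 1
}

same_grid <- function(a, b) {
  identical(dim(a$data), dim(b$data)) &&
    isTRUE(all.equal(a$spacing, b$spacing)) &&
    isTRUE(all.equal(a$origin, b$origin))
}
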