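#' Preprocessing configuration
#'
#' @param target_spacing_mm per-axis voxel size after spacing
#'   normalization (mm). The default matches the in-plane resolution and
#'   slice thickness of a typical PVP acquisition.
#' @param patch_shape sliding-window patch size in voxels.
#' @param patch_overlap_fraction fractional overlap between neighbouring
#'   windows, in `[0, 1)`.
#' @param clip_percentiles intensity percentiles clipped before
#'   z-normalization, to tame MR outliers.
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(target_spacing_mm = c(1.5, 1.5, 3),
                              patch_shape = c(160L, 160L, 160L),
                              patch_overlap_fraction = 0.5,
                              clip_percentiles = c(0.005, 0.995)) {
  stopifnot(all(target_spacing_mm > 0), all(patch_shape > 0),
            patch_overlap_fraction >= 0, patch_overlap_fraction < 1,
            length(clip_percentiles) == 2,
            clip_percentiles[1] < clip_percentiles[2])
  structure(list(target_spacing_mm = as.numeric(target_spacing_mm),
                 patch_shape = as.integer(patch_shape),
                 patch_overlap_fraction = patch_overlap_fraction,
                 clip_percentiles = as.numeric(clip_percentiles)),
            class = "preprocess_config")
}

#' Resample a volume to a target spacing
#'
#' Trilinear (images) or nearest-neighbour (label maps) resampling onto a
#' grid with the requested spacing and the same origin; the output shape is
#' chosen so the physical extent is preserved within one output voxel per
#' axis.
#'
#' @param volume a [vol_grid()] or [label_map()].
#' @param target_spacing_mm numeric length-3 (mm), all positive.
#' @param interpolation `"linear"` or `"nearest"`; label maps always use
#'   nearest.
#' @return resampled volume of the same class.
#' @export
resample_to_spacing <- function(volume, target_spacing_mm,
                                interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  if (any(target_spacing_mm <= 0)) {
    stop("configuration error: target spacing must be positive")
  }
  is_labels <- inherits(volume, "label_map")
  if (is_labels) interpolation <- "nearest"
  if (isTRUE(all.equal(volume$spacing, as.numeric(target_spacing_mm)))) {
    return(volume)   # identical grid: both schemes are the identity
  }
  in_dim <- dim(volume$data)
  out_dim <- pmax(1L, as.integer(round(in_dim * volume$spacing /
                                         target_spacing_mm)))
  out <- resample_onto(volume, out_dim, target_spacing_mm, volume$origin,
                       interpolation)
  if (is_labels) label_map(out, target_spacing_mm, volume$origin)
  else vol_grid(out, target_spacing_mm, volume$origin)
}

# Sample `volume` at the voxel centres of an arbitrary axis-aligned grid.
resample_onto <- function(volume, out_dim, out_spacing, out_origin,
                          interpolation) {
  in_dim <- dim(volume$data)
  cont <- lapply(1:3, function(k) {
    w <- out_origin[k] + (seq_len(out_dim[k]) - 1) * out_spacing[k]
    (w - volume$origin[k]) / volume$spacing[k] + 1   # continuous 1-based
  })
  if (interpolation == "nearest") {
    ii <- lapply(1:3, function(k) pmin(pmax(round(cont[[k]]), 1), in_dim[k]))
    return(array(volume$data[ii[[1]], ii[[2]], ii[[3]]], out_dim))
  }
  lo <- lapply(1:3, function(k) pmin(pmax(floor(cont[[k]]), 1), in_dim[k]))
  hi <- lapply(1:3, function(k) pmin(lo[[k]] + 1, in_dim[k]))
  fr <- lapply(1:3, function(k) pmin(pmax(cont[[k]] - lo[[k]], 0), 1))
  acc <- array(0, out_dim)
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    wx <- if (cx) fr[[1]] else 1 - fr[[1]]
    wy <- if (cy) fr[[2]] else 1 - fr[[2]]
    wz <- if (cz) fr[[3]] else 1 - fr[[3]]
    w <- outer(outer(wx, wy), wz)
    ix <- if (cx) hi[[1]] else lo[[1]]
    iy <- if (cy) hi[[2]] else lo[[2]]
    iz <- if (cz) hi[[3]] else lo[[3]]
    acc <- acc + w * array(volume$data[ix, iy, iz], out_dim)
  }
  acc
}

#' Grayscale z-normalization
#'
#' Subtracts the volume mean and divides by the volume standard deviation,
#' computed over all voxels.
#'
#' @param volume a [vol_grid()] with more than one voxel.
#' @return normalized [vol_grid()] (mean 0, sd 1).
#' @export
zscore_normalize <- function(volume) {
  stopifnot(length(volume$data) > 1)
  s <- sd(volume$data)
  if (s == 0) stop("degenerate input: zero-variance volume")
  vol_grid((volume$data - mean(volume$data)) / s, volume$spacing,
           volume$origin)
}

clip_intensities <- function(volume, probs) {
  q <- quantile(volume$data, probs, names = FALSE)
  vol_grid(pmin(pmax(volume$data, q[1]), q[2]), volume$spacing,
           volume$origin)
}

sliding_starts <- function(len, patch, stride) {
  if (patch >= len) return(0L)
  s <- seq(0L, len - patch, by = stride)
  if (s[length(s)] + patch < len) s <- c(s, len - patch)
  as.integer(s)
}

#' Sliding-window patch extraction
#'
#' Tiles the volume with fixed-shape windows at stride
#' `patch_shape * (1 - overlap_fraction)`; the last window per axis is
#' clamped to the boundary so the union of windows covers every voxel.
#' Volumes smaller than the patch are zero-padded symmetrically.
#'
#' @param volume a [vol_grid()] (or plain 3D array).
#' @param patch_shape integer length-3.
#' @param overlap_fraction in `[0, 1)`.
#' @return list with `patches` (list of `list(data, offset)`, offsets
#'   0-based voxel offsets into the padded volume), `padded_dim`, and `pad`
#'   (0-based voxel offset of the original volume inside the padded one).
#' @export
sliding_window_patches <- function(volume, patch_shape,
                                   overlap_fraction = 0.5) {
  a <- if (inherits(volume, "vol_grid")) volume$data else volume
  patch_shape <- as.integer(patch_shape)
  d <- dim(a)
  pad_lo <- pmax(0L, as.integer(floor((patch_shape - d) / 2)))
  pad_hi <- pmax(0L, patch_shape - d - pad_lo)
  if (any(pad_lo + pad_hi > 0L)) {
    padded <- array(0, d + pad_lo + pad_hi)
    padded[pad_lo[1] + seq_len(d[1]), pad_lo[2] + seq_len(d[2]),
           pad_lo[3] + seq_len(d[3])] <- a
    a <- padded
    d <- dim(a)
  }
  stride <- pmax(1L, as.integer(round(patch_shape * (1 - overlap_fraction))))
  starts <- lapply(1:3, function(k) sliding_starts(d[k], patch_shape[k],
                                                   stride[k]))
  grid <- expand.grid(x = starts[[1]], y = starts[[2]], z = starts[[3]])
  patches <- lapply(seq_len(nrow(grid)), function(i) {
    off <- as.integer(grid[i, ])
    list(data = a[off[1] + seq_len(patch_shape[1]),
                  off[2] + seq_len(patch_shape[2]),
                  off[3] + seq_len(patch_shape[3]), drop = FALSE],
         offset = off)
  })
  list(patches = patches, padded_dim = d, pad = pad_lo)
}

#' Fuse per-patch class probabilities into a full volume
#'
#' Per-voxel average of all covering patch probabilities, renormalized so
#' the class probabilities sum to one at each voxel.
#'
#' @param patches list of `list(probs, offset)` where `probs` is a 4D array
#'   (patch dims x classes) and `offset` the 0-based voxel offset.
#' @param full_shape integer length-3 of the (padded) volume.
#' @return 4D array `full_shape x classes` of fused probabilities.
#' @export
fuse_patch_predictions <- function(patches, full_shape) {
  stopifnot(length(patches) > 0)
  ncls <- dim(patches[[1]]$probs)[4]
  acc <- array(0, c(full_shape, ncls))
  cnt <- array(0, full_shape)
  for (p in patches) {
    pd <- dim(p$probs)[1:3]
    ix <- p$offset[1] + seq_len(pd[1])
    iy <- p$offset[2] + seq_len(pd[2])
    iz <- p$offset[3] + seq_len(pd[3])
    acc[ix, iy, iz, ] <- acc[ix, iy, iz, ] + p$probs
    cnt[ix, iy, iz] <- cnt[ix, iy, iz] + 1
  }
  if (any(cnt == 0)) stop("internal error: voxel covered by no patch")
  acc <- acc / array(rep(cnt, ncls), dim(acc))
  tot <- apply(acc, c(1, 2, 3), sum)
  acc / array(rep(pmax(tot, 1e-12), ncls), dim(acc))
}
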