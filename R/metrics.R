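#' Extract the surface of a binary region
#'
#' Surface voxels are region voxels with at least one six-connected
#' background neighbour (array borders count as background). Coordinates
#' are voxel centres in physical mm, so anisotropic spacing is honoured.
#'
#' @param region binary [vol_grid()].
#' @return an n x 3 matrix of mm coordinates (class `surface_set`), possibly
#'   with zero rows for an empty region.
#' @export
extract_surface <- function(region) {
  m <- region$data > 0
  shell <- m & !erode6(m)
  idx <- which(shell)
  pts <- voxel_coords_mm(region, arrayInd(idx, dim(m)))
  structure(pts, class = c("surface_set", class(pts)))
}

#' Dice similarity coefficient (percent)
#'
#' `2|X n Y| / (|X| + |Y|) x 100`; 0 means no overlap, 100 full overlap.
#' Two empty regions agree perfectly and return 100.
#'
#' @param X,Y binary [vol_grid()]s on the same grid.
#' @return percentage in `[0, 100]`.
#' @export
dsc <- function(X, Y) {
  stopifnot(same_grid(X, Y))
  x <- X$data > 0; y <- Y$data > 0
  nx <- sum(x); ny <- sum(y)
  if (nx + ny == 0) {
    message("dsc: both regions empty; returning 100 (agreement on absence)")
    return(100)
  }
  200 * sum(x & y) / (nx + ny)
}

surface_stats <- function(X, Y) {
  sx <- extract_surface(X)
  sy <- extract_surface(Y)
  if (nrow(sx) == 0 || nrow(sy) == 0) {
    stop("undefined metric: empty surface")
  }
  .cpp_surface_dist_stats(unclass(sx), unclass(sy))
}

#' Mean surface distance (mm)
#'
#' The symmetric mean of nearest-neighbour Euclidean distances between the
#' two region surfaces:
#' `(sum_x min_y d(x,y) + sum_y min_x d(x,y)) / (N_X + N_Y)`.
#'
#' @inheritParams dsc
#' @return distance in mm.
#' @export
msd <- function(X, Y) {
  st <- surface_stats(X, Y)
  (st$sum_x + st$sum_y) / (st$n_x + st$n_y)
}

#' Hausdorff distance (mm)
#'
#' `max(hd(X,Y), hd(Y,X))` where `hd(X,Y) = max_x min_y d(x,y)` over the
#' surface point sets, Euclidean mm.
#'
#' @inheritParams dsc
#' @return distance in mm.
#' @export
hd <- function(X, Y) {
  st <- surface_stats(X, Y)
  max(st$max_x, st$max_y)
}

#' Volume ratio
#'
#' `V_X / V_Y` with volumes in mm^3 (voxel count x voxel volume).
#'
#' @inheritParams dsc
#' @return dimensionless ratio.
#' @export
rv <- function(X, Y) {
  stopifnot(same_grid(X, Y))
  vy <- sum(Y$data > 0) * voxel_volume_mm3(Y)
  if (vy == 0) stop("undefined metric: reference volume is zero")
  sum(X$data > 0) * voxel_volume_mm3(X) / vy
}

binary_region <- function(lab_map, label) {
  vol_grid((lab_map$data == label) * 1, lab_map$spacing, lab_map$origin)
}

#' Evaluate a predicted segment map against a reference
#'
#' Computes DSC (%), MSD (mm), HD (mm) and RV for each label 1-8 plus the
#' unweighted mean over the eight segments. Labels absent from the
#' reference are flagged missing and excluded from the averages.
#'
#' @param pred,ref [label_map()]s on the same grid.
#' @param case optional case identifier recorded in the output.
#' @return a `data.frame` with columns `case`, `label` (\"S1\"..\"S8\",
#'   \"AVG\"), `DSC_pct`, `MSD_mm`, `HD_mm`, `RV`.
#' @export
evaluate_segmentation <- function(pred, ref, case = "case") {
  stopifnot(same_grid(pred, ref))
  rows <- lapply(1:8, function(l) {
    pr <- binary_region(pred, l)
    rf <- binary_region(ref, l)
    if (!any(rf$data > 0)) {
      message("label S", l, " absent from reference; excluded from AVG")
      return(data.frame(case = case, label = paste0("S", l), DSC_pct = NA,
                        MSD_mm = NA, HD_mm = NA, RV = NA))
    }
    has_pred <- any(pr$data > 0)
    data.frame(case = case, label = paste0("S", l),
               DSC_pct = dsc(pr, rf),
               MSD_mm = if (has_pred) msd(pr, rf) else NA,
               HD_mm = if (has_pred) hd(pr, rf) else NA,
               RV = rv(pr, rf))
  })
  per <- do.call(rbind, rows)
  avg <- data.frame(case = case, label = "AVG",
                    DSC_pct = mean(per$DSC_pct, na.rm = TRUE),
                    MSD_mm = mean(per$MSD_mm, na.rm = TRUE),
                    HD_mm = mean(per$HD_mm, na.rm = TRUE),
                    RV = mean(per$RV, na.rm = TRUE))
  out <- rbind(per, avg)
  rownames(out) <- NULL
  out
}
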