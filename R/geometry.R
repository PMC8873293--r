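#' Fit a plane to 3D points by total least squares
#'
#' The plane minimises the sum of squared orthogonal distances to the
#' points. The normal is the singular vector of the centred point matrix
#' with the smallest singular value, oriented so that its first nonzero
#' component (checking x, then y, then z) is positive.
#'
#' @param points n x 3 matrix of mm coordinates, n >= 3, not all collinear.
#' @param role optional role tag, one of `"MID"`, `"RHV"`, `"LHV_LLF"`,
#'   `"RPV_H"`, `"LPV_H"`.
#' @return a `couinaud_plane`: list with `point` (centroid), unit `normal`,
#'   and `role`.
#' @export
fit_plane <- function(points, role = NULL) {
  points <- matrix(as.numeric(points), ncol = 3)
  if (nrow(points) < 3) {
    stop("degenerate geometry: a plane fit needs at least 3 points")
  }
  ctr <- colMeans(points)
  X <- sweep(points, 2, ctr)
  sv <- svd(X, nu = 0, nv = 3)
  # collinear (or coincident) points leave two near-zero singular values
  scale <- max(sv$d[1], .Machine$double.eps)
  if (sv$d[2] / scale < 1e-9) {
    stop("degenerate geometry: points are collinear")
  }
  normal <- sv$v[, 3]
  normal <- orient_normal(normal)
  structure(list(point = ctr, normal = normal, role = role),
            class = "couinaud_plane")
}

orient_normal <- function(normal, tol = 1e-12) {
  normal <- normal / sqrt(sum(normal^2))
  for (i in 1:3) {
    if (abs(normal[i]) > tol) {
      if (normal[i] < 0) normal <- -normal
      break
    }
  }
  normal
}

#' Signed distance from points to a plane
#'
#' `dot(p - plane$point, plane$normal)` in mm; the sign follows the plane's
#' normal orientation.
#'
#' @param point_mm length-3 vector or n x 3 matrix of mm coordinates.
#' @param plane a `couinaud_plane` from [fit_plane()].
#' @return scalar or vector of signed distances (mm).
#' @export
signed_distance <- function(point_mm, plane) {
  p <- matrix(point_mm, ncol = 3)
  drop(sweep(p, 2, plane$point) %*% plane$normal)
}

axial_plane <- function(level_z, role) {
  structure(list(point = c(0, 0, level_z), normal = c(0, 0, 1), role = role),
            class = "couinaud_plane")
}

ivc_midpoint <- function(landmarks) {
  ivc <- landmarks$IVC
  ivc[(nrow(ivc) + 1L) %/% 2L, ]
}

# linear interpolation of a polyline parameterized by its z coordinate
interp_polyline_z <- function(poly, z) {
  ord <- order(poly[, 3])
  poly <- poly[ord, , drop = FALSE]
  cbind(approx(poly[, 3], poly[, 1], xout = z, rule = 2)$y,
        approx(poly[, 3], poly[, 2], xout = z, rule = 2)$y,
        z)
}

#' Build the five Couinaud separating planes from landmarks
#'
#' Realizes the five-divider protocol: the MID plane through the IVC
#' midpoint, the middle hepatic vein and the gallbladder-fossa vertex
#' (right/left lobe divider); the RHV plane through the right hepatic vein
#' and the IVC midpoint (right anterior/posterior divider); the LHV_LLF
#' plane through the left hepatic vein above the left-portal axial level
#' and the left longitudinal fissure below it (left medial/lateral
#' divider); and two horizontal (axial) planes at the right-portal main
#' stem and sagittal left-portal levels (superior/inferior dividers).
#'
#' @param landmarks a [landmark_set()].
#' @param liver_mask optional binary [vol_grid()] (unused by the fits; kept
#'   for interface symmetry with the labeler).
#' @return named list of five `couinaud_plane`s:
#'   `MID`, `RHV`, `LHV_LLF`, `RPV_H`, `LPV_H`.
#' @export
build_separating_planes <- function(landmarks, liver_mask = NULL) {
  required <- c("IVC", "MHV", "RHV", "LHV", "LLF", "GB_vertex", "RPV",
                "LPV_sag", "VL_fissure")
  missing <- setdiff(required, names(landmarks))
  if (length(missing)) {
    stop("landmark error: missing ", paste(missing, collapse = ", "))
  }
  mid0 <- ivc_midpoint(landmarks)
  lpv_z <- landmarks$LPV_sag[3]
  rpv_z <- landmarks$RPV[3]

  mid <- fit_plane(rbind(mid0, landmarks$MHV, landmarks$GB_vertex),
                   role = "MID")
  rhv <- fit_plane(rbind(landmarks$RHV, mid0), role = "RHV")
  lhv_pts <- landmarks$LHV[landmarks$LHV[, 3] >= lpv_z, , drop = FALSE]
  llf_pts <- landmarks$LLF[landmarks$LLF[, 3] <= lpv_z, , drop = FALSE]
  lhv_llf <- fit_plane(rbind(lhv_pts, llf_pts), role = "LHV_LLF")

  list(MID = mid, RHV = rhv, LHV_LLF = lhv_llf,
       RPV_H = axial_plane(rpv_z, "RPV_H"),
       LPV_H = axial_plane(lpv_z, "LPV_H"))
}

# Orient a fitted vertical plane's normal for side classification:
# near-sagittal dividers (MID, LHV_LLF) point towards +x (anatomical right),
# the RHV divider towards +y (anterior). Positive signed distance then means
# "right of" resp. "anterior of" the divider.
role_oriented_normal <- function(plane) {
  n <- plane$normal
  axis <- switch(plane$role, MID = 1L, LHV_LLF = 1L, RHV = 2L, 3L)
  if (n[axis] < 0) n <- -n
  n
}

#' Carve out the caudate lobe (S1)
#'
#' S1 is delimited by the surface swept from the venous-ligament fissure to
#' the right wall of the IVC: within the axial range where the fissure is
#' defined, a liver voxel belongs to S1 when it lies dorsal (posterior) to
#' the line joining the fissure to the IVC right wall on its slice, with x
#' between the fissure and the IVC right wall. The IVC right wall is the
#' IVC centreline offset by the IVC radius in +x.
#'
#' @param landmarks a [landmark_set()] with `VL_fissure` and `IVC`.
#' @param liver_mask binary [vol_grid()].
#' @return binary [vol_grid()]; empty (with a warning) when the fissure
#'   falls outside the liver.
#' @export
caudate_region <- function(landmarks, liver_mask) {
  vl <- landmarks$VL_fissure
  zr <- range(vl[, 3])
  ivc_r <- landmarks$ivc_radius_mm %||% 8
  d <- dim(liver_mask$data)
  out <- array(FALSE, d)
  zs <- axis_coords_mm(liver_mask, 3)
  xs <- axis_coords_mm(liver_mask, 1)
  ys <- axis_coords_mm(liver_mask, 2)
  in_z <- which(zs >= zr[1] & zs <= zr[2])
  for (k in in_z) {
    fz <- interp_polyline_z(vl, zs[k])[1, ]
    wz <- interp_polyline_z(landmarks$IVC, zs[k])[1, ]
    wz[1] <- wz[1] + ivc_r
    x0 <- min(fz[1], wz[1]); x1 <- max(fz[1], wz[1])
    if (x1 - x0 < 1e-9) next
    # dorsal side of the fissure-to-wall chord: y at or below the chord
    ycut <- fz[2] + (xs - fz[1]) * (wz[2] - fz[2]) / (wz[1] - fz[1])
    in_x <- xs >= x0 & xs <= x1                 # length d[1]
    below_chord <- outer(ycut, ys, `>=`)        # d[1] x d[2]
    out[, , k] <- (liver_mask$data[, , k] > 0) & in_x & below_chord
  }
  if (!any(out)) {
    warning("caudate region is empty")
  }
  vol_grid(out * 1, liver_mask$spacing, liver_mask$origin)
}

#' Assign Couinaud segment labels to a liver mask
#'
#' Every liver voxel receives exactly one label 1-8. The caudate (S1) is
#' carved out first from the venous-ligament-fissure surface; the remaining
#' voxels are classified by signed distances to the five separating planes:
#' left of MID and lateral of LHV_LLF gives S2 (above the LPV level) or S3
#' (below); left of MID and medial gives S4; right of MID and anterior of
#' RHV gives S8 (above the RPV level) or S5 (below); posterior of RHV gives
#' S7 (above) or S6 (below). Membership is decided at voxel centres in mm;
#' exact ties on a divider resolve towards the lower segment number.
#'
#' @param liver_mask binary [vol_grid()].
#' @param landmarks a [landmark_set()].
#' @param planes optional precomputed list from [build_separating_planes()].
#' @return a [label_map()] on the same grid.
#' @export
assign_couinaud_labels <- function(liver_mask, landmarks, planes = NULL) {
  planes <- planes %||% build_separating_planes(landmarks, liver_mask)
  s1 <- suppressWarnings(caudate_region(landmarks, liver_mask))
  d <- dim(liver_mask$data)
  lab <- array(0L, d)

  liver_idx <- which(liver_mask$data > 0)
  if (!length(liver_idx)) {
    return(label_map(lab, liver_mask$spacing, liver_mask$origin))
  }
  pts <- voxel_coords_mm(liver_mask, arrayInd(liver_idx, d))

  n_mid <- role_oriented_normal(planes$MID)
  n_rhv <- role_oriented_normal(planes$RHV)
  n_lhv <- role_oriented_normal(planes$LHV_LLF)
  sd_mid <- drop(sweep(pts, 2, planes$MID$point) %*% n_mid)
  sd_rhv <- drop(sweep(pts, 2, planes$RHV$point) %*% n_rhv)
  sd_lhv <- drop(sweep(pts, 2, planes$LHV_LLF$point) %*% n_lhv)
  z <- pts[, 3]
  lpv_z <- planes$LPV_H$point[3]
  rpv_z <- planes$RPV_H$point[3]

  v <- integer(length(liver_idx))
  left <- sd_mid <= 0
  lateral <- left & sd_lhv <= 0
  v[lateral & z >= lpv_z] <- 2L
  v[lateral & z < lpv_z] <- 3L
  v[left & sd_lhv > 0] <- 4L
  right <- !left
  below <- z <= rpv_z
  v[right & below & sd_rhv >= 0] <- 5L
  v[right & below & sd_rhv < 0] <- 6L
  v[right & !below & sd_rhv <= 0] <- 7L
  v[right & !below & sd_rhv > 0] <- 8L
  lab[liver_idx] <- v
  lab[s1$data > 0 & liver_mask$data > 0] <- 1L

  if (any(lab[liver_idx] == 0L)) {
    stop("internal consistency error: unlabeled liver voxel")
  }
  label_map(lab, liver_mask$spacing, liver_mask$origin)
}
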