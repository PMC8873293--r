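#' @keywords internal
# label groups adjacent to each separating plane
plane_label_groups <- function(role) {
  switch(role,
         MID = list(a = c(2L, 3L, 4L), b = c(5L, 6L, 7L, 8L)),
         RHV = list(a = c(5L, 8L), b = c(6L, 7L)),
         LHV_LLF = list(a = c(2L, 3L), b = 4L),
         RPV_H = list(a = c(5L, 6L), b = c(7L, 8L)),
         LPV_H = list(a = 3L, b = 2L),
         stop("unknown plane role: ", role))
}

# voxels of group `a` with a 6-neighbour in group `b` (and vice versa)
group_boundary_voxels <- function(lab_map, groups) {
  a <- lab_map$data
  ga <- array(a %in% groups$a, dim(a))
  gb <- array(a %in% groups$b, dim(a))
  d <- dim(a)
  touch <- array(FALSE, d)
  pair <- function(x, y) x & y
  touch[-d[1], , ] <- touch[-d[1], , ] | pair(ga[-d[1], , ], gb[-1, , ]) |
    pair(gb[-d[1], , ], ga[-1, , ])
  touch[-1, , ] <- touch[-1, , ] | pair(ga[-1, , ], gb[-d[1], , ]) |
    pair(gb[-1, , ], ga[-d[1], , ])
  touch[, -d[2], ] <- touch[, -d[2], ] | pair(ga[, -d[2], ], gb[, -1, ]) |
    pair(gb[, -d[2], ], ga[, -1, ])
  touch[, -1, ] <- touch[, -1, ] | pair(ga[, -1, ], gb[, -d[2], ]) |
    pair(gb[, -1, ], ga[, -d[2], ])
  touch[, , -d[3]] <- touch[, , -d[3]] | pair(ga[, , -d[3]], gb[, , -1]) |
    pair(gb[, , -d[3]], ga[, , -1])
  touch[, , -1] <- touch[, , -1] | pair(ga[, , -1], gb[, , -d[3]]) |
    pair(gb[, , -1], ga[, , -d[3]])
  which(touch)
}

#' Measure how far a separating plane shifted between two segmentations
#'
#' For the vertical dividers (MID, RHV, LHV_LLF) a total-least-squares
#' plane is fitted to the inter-segment boundary voxels of the relevant
#' label pair in each map; the magnitude is the distance (mm) from the
#' reference plane, evaluated at the liver centroid projected onto it, to
#' the fitted plane of the prediction. For the horizontal dividers (RPV_H,
#' LPV_H) the magnitude is the absolute difference of the median boundary
#' slice index, in slices.
#'
#' @param pred,ref [label_map()]s on the same grid.
#' @param plane_role one of `"MID"`, `"RHV"`, `"LHV_LLF"`, `"RPV_H"`,
#'   `"LPV_H"`.
#' @return shift magnitude (mm for vertical roles, slices for horizontal);
#'   `Inf` (with a warning) when the boundary is missing in either map.
#' @export
measure_plane_shift <- function(pred, ref, plane_role) {
  stopifnot(same_grid(pred, ref))
  groups <- plane_label_groups(plane_role)
  bp <- group_boundary_voxels(pred, groups)
  br <- group_boundary_voxels(ref, groups)
  if (length(bp) < 3L || length(br) < 3L) {
    warning("boundary for ", plane_role,
            " missing or degenerate; shift unmeasurable (treated as severe)")
    return(Inf)
  }
  d <- dim(ref$data)
  if (plane_role %in% c("RPV_H", "LPV_H")) {
    zp <- median(arrayInd(bp, d)[, 3])
    zr <- median(arrayInd(br, d)[, 3])
    return(abs(zp - zr))
  }
  pts_p <- voxel_coords_mm(pred, arrayInd(bp, d))
  pts_r <- voxel_coords_mm(ref, arrayInd(br, d))
  pl_p <- fit_plane(pts_p, role = plane_role)
  pl_r <- fit_plane(pts_r, role = plane_role)
  liver <- which(ref$data > 0)
  ctr <- colMeans(voxel_coords_mm(ref, arrayInd(liver, d)))
  anchor <- ctr - signed_distance(ctr, pl_r) * pl_r$normal
  abs(signed_distance(anchor, pl_p))
}

#' Grade a plane shift
#'
#' Vertical dividers (mm): slight when at most 5, severe when at least 10,
#' moderate between. Horizontal dividers (slices): slight when at most 2,
#' severe when at least 5, moderate between.
#'
#' @param magnitude shift magnitude (>= 0); mm or slices per role.
#' @param plane_role the divider the shift belongs to.
#' @return `"slight"`, `"moderate"` or `"severe"`.
#' @export
grade_shift <- function(magnitude, plane_role) {
  stopifnot(magnitude >= 0)
  groups <- plane_label_groups(plane_role)  # validates the role
  horizontal <- plane_role %in% c("RPV_H", "LPV_H")
  lo <- if (horizontal) 2 else 5
  hi <- if (horizontal) 5 else 10
  if (magnitude <= lo) "slight" else if (magnitude >= hi) "severe"
  else "moderate"
}

ref_divider_boundary <- function(ref) {
  unique(unlist(lapply(c("MID", "RHV", "LHV_LLF", "RPV_H", "LPV_H"),
                       function(role) {
                         group_boundary_voxels(ref,
                                               plane_label_groups(role))
                       })))
}

#' Detect inter-segment segmentation faults
#'
#' A fault is a labeling error that cannot be explained by a misplaced
#' separating plane: a connected component of mislabeled liver voxels
#' (prediction and reference both nonzero but different) whose volume
#' reaches `min_volume_mm3` and whose centroid lies at least
#' `min_distance_mm` from every reference inter-segment boundary.
#'
#' @param pred,ref [label_map()]s on the same grid.
#' @param min_volume_mm3 component volume threshold (default 1 cm^3).
#' @param min_distance_mm centroid-to-boundary threshold (default 10 mm).
#' @return logical.
#' @export
detect_fault <- function(pred, ref, min_volume_mm3 = 1000,
                         min_distance_mm = 10) {
  stopifnot(same_grid(pred, ref))
  mis <- pred$data != ref$data & pred$data > 0L & ref$data > 0L
  if (!any(mis)) return(FALSE)
  comp <- label_components(mis, 26L)
  d <- dim(comp)
  bnd <- ref_divider_boundary(ref)
  if (!length(bnd)) return(TRUE)
  bnd_pts <- voxel_coords_mm(ref, arrayInd(bnd, d))
  vvol <- voxel_volume_mm3(ref)
  for (k in seq_len(max(comp))) {
    vox <- which(comp == k)
    if (length(vox) * vvol < min_volume_mm3) next
    ctr <- colMeans(voxel_coords_mm(ref, arrayInd(vox, d)))
    dmin <- sqrt(min(rowSums(sweep(bnd_pts, 2, ctr)^2)))
    if (dmin >= min_distance_mm) return(TRUE)
  }
  FALSE
}

#' Overall segmentation quality from shift grades and fault flag
#'
#' Rules: any severe shift or an inter-segment fault gives `"poor"`. With
#' neither, `"good"` requires at most two (nonzero) slight shifts and no
#' moderate shift, or exactly one moderate shift and no nonzero slight
#' shift; everything else is `"moderate"`. A zero-magnitude shift grades
#' `"none"` and never counts against the rules.
#'
#' @param grades character vector of exactly five grades from
#'   `{"none", "slight", "moderate", "severe"}`, one per divider.
#' @param fault logical fault flag from [detect_fault()].
#' @return `"good"`, `"moderate"` or `"poor"`.
#' @export
classify_quality <- function(grades, fault) {
  if (length(grades) != 5L) {
    stop("exactly five plane grades are required")
  }
  if (!all(grades %in% c("none", "slight", "moderate", "severe"))) {
    stop("unknown grade value")
  }
  if (any(grades == "severe") || isTRUE(fault)) return("poor")
  n_slight <- sum(grades == "slight")
  n_mod <- sum(grades == "moderate")
  if ((n_mod == 0L && n_slight <= 2L) || (n_mod == 1L && n_slight == 0L)) {
    return("good")
  }
  "moderate"
}

#' Full qualitative report for a predicted segmentation
#'
#' Measures all five plane shifts, grades them (zero magnitude grades
#' `"none"`), detects faults, and classifies overall quality.
#'
#' @param pred,ref [label_map()]s on the same grid.
#' @return a `quality_report`: list with `shifts` (data.frame of role,
#'   magnitude, unit, grade), `fault`, `overall`.
#' @export
quality_report <- function(pred, ref) {
  roles <- c("MID", "RHV", "LHV_LLF", "RPV_H", "LPV_H")
  shifts <- do.call(rbind, lapply(roles, function(role) {
    m <- suppressWarnings(measure_plane_shift(pred, ref, role))
    # magnitudes at numerical-noise level count as no shift
    g <- if (m <= 1e-6) "none" else grade_shift(m, role)
    data.frame(plane_role = role, magnitude = m,
               unit = if (role %in% c("RPV_H", "LPV_H")) "slices" else "mm",
               grade = g)
  }))
  fault <- detect_fault(pred, ref)
  structure(list(shifts = shifts, fault = fault,
                 overall = classify_quality(shifts$grade, fault)),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat("<quality_report> overall:", x$overall,
      if (x$fault) "(inter-segment fault)" else "", "\n")
  print(x$shifts)
  invisible(x)
}

#' Select the lesions eligible for indirect evaluation
#'
#' Drops lesions with diameter <= 5 mm; when more than five remain, keeps
#' the five largest by diameter (ties broken by lower id).
#'
#' @param lesions list of `lesion` objects.
#' @return filtered list (possibly empty).
#' @export
filter_lesions <- function(lesions) {
  keep <- Filter(function(l) l$diameter_mm > 5, lesions)
  if (length(keep) > 5L) {
    ord <- order(-vapply(keep, `[[`, 0, "diameter_mm"),
                 vapply(keep, `[[`, 0L, "id"))
    keep <- keep[ord[1:5]]
  }
  keep
}

#' Localize a lesion from a predicted segment map
#'
#' Assigns the lesion to every predicted segment covering at least
#' `min_fraction` of its voxels, always including the modal segment. A
#' lesion wholly outside the predicted liver is unlocalizable and returns
#' an empty set (counted as a failure downstream).
#'
#' @param lesion a `lesion` object (voxel indices on `pred`'s grid).
#' @param pred a [label_map()].
#' @param min_fraction assignment threshold (default 0.1).
#' @return the lesion with `assigned_segments` set (integer vector, sorted;
#'   empty when unlocalizable).
#' @export
localize_lesion <- function(lesion, pred, min_fraction = 0.1) {
  lv <- pred$data[lesion$voxels]
  lv <- lv[lv > 0L]
  if (!length(lv)) {
    lesion$assigned_segments <- integer(0)
    return(lesion)
  }
  frac <- table(lv) / length(lesion$voxels)
  modal <- as.integer(names(frac)[which.max(frac)])
  assigned <- sort(unique(c(modal,
                            as.integer(names(frac)[frac >= min_fraction]))))
  lesion$assigned_segments <- assigned
  lesion
}

#' Lesion localization accuracy over a case set
#'
#' Applies the eligibility filter and localization to each case and scores
#' a lesion correct when its assigned segment set equals its true set.
#'
#' @param lesions list of `lesion` objects.
#' @param pred a [label_map()].
#' @param min_fraction see [localize_lesion()].
#' @return list with `n`, `n_correct`, `accuracy` (fraction), and the
#'   localized lesions.
#' @export
localization_accuracy <- function(lesions, pred, min_fraction = 0.1) {
  eligible <- filter_lesions(lesions)
  loc <- lapply(eligible, localize_lesion, pred = pred,
                min_fraction = min_fraction)
  correct <- vapply(loc, function(l) {
    length(l$assigned_segments) > 0 &&
      identical(l$assigned_segments, l$true_segments)
  }, logical(1))
  list(n = length(loc), n_correct = sum(correct),
       accuracy = if (length(loc)) mean(correct) else NA_real_,
       lesions = loc)
}

#' Linearly weighted Cohen's kappa
#'
#' Chance-corrected agreement for ordered categories with linear weights
#' `w_ij = |i - j| / (k - 1)`:
#' `kappa_w = 1 - sum(w O) / sum(w E)` with observed proportions `O` and
#' chance-expected proportions `E` from the marginals. Equals unweighted
#' kappa when `k = 2`.
#'
#' @param ratings_a,ratings_b equal-length vectors of ratings.
#' @param categories_ordered the ordered category levels (e.g.
#'   `c("good", "moderate", "poor")`).
#' @return kappa in `[-1, 1]`.
#' @export
weighted_kappa <- function(ratings_a, ratings_b, categories_ordered) {
  if (length(ratings_a) != length(ratings_b) || length(ratings_a) < 2) {
    stop("need two equal-length rating vectors with >= 2 ratings")
  }
  if (!all(c(ratings_a, ratings_b) %in% categories_ordered)) {
    stop("unknown category in ratings")
  }
  k <- length(categories_ordered)
  fa <- factor(ratings_a, levels = categories_ordered)
  fb <- factor(ratings_b, levels = categories_ordered)
  O <- table(fa, fb) / length(fa)
  Ea <- table(fa) / length(fa)
  Eb <- table(fb) / length(fb)
  E <- outer(as.numeric(Ea), as.numeric(Eb))
  W <- abs(outer(seq_len(k), seq_len(k), `-`)) / (k - 1)
  1 - sum(W * O) / sum(W * E)
}
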