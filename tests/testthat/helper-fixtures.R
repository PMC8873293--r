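# Shared fixtures and independent oracles, built in code.

# A cubic "liver" with exactly axis-aligned dividers placed between voxel
# centres, plus a landmark set whose fitted planes reproduce them.
cube_fixture <- function(n = 20L, spacing = c(1, 1, 1)) {
  mask <- vol_grid(array(1, c(n, n, n)), spacing)
  mid_x <- (n - 1) / 2        # between voxel centres for even n
  lhv_x <- mid_x / 2
  rhv_y <- (n - 1) / 2
  rpv_z <- (n - 1) / 2
  lpv_z <- rpv_z
  # vertical planes realized through exactly planar landmark polylines;
  # the IVC runs along the MID/RHV plane intersection
  ivc <- cbind(mid_x, rhv_y, seq(1, n - 2))
  mhv <- cbind(mid_x, seq(2, n - 2, length.out = 4), n / 2)
  gb <- c(mid_x, n - 2, 1)
  rhv <- cbind(seq(mid_x + 1, n - 2, length.out = 4), rhv_y, n / 2)
  lhv <- cbind(lhv_x, seq(1, n - 2, length.out = 4),
               seq(lpv_z + 1, n - 2, length.out = 4))
  llf <- cbind(lhv_x, seq(1, n - 2, length.out = 4),
               seq(1, lpv_z - 1, length.out = 4))
  vl <- cbind(rep(-50, 2), -50, c(-50, -49))  # far outside: no caudate
  lm <- landmark_set(IVC = ivc, MHV = mhv, RHV = rhv, LHV = lhv, LLF = llf,
                     GB_vertex = gb, RPV = c(mid_x + 2, 2, rpv_z),
                     LPV_sag = c(lhv_x - 1, 2, lpv_z), VL_fissure = vl,
                     ivc_radius_mm = 1)
  list(mask = mask, landmarks = lm, mid_x = mid_x, lhv_x = lhv_x,
       rhv_y = rhv_y, rpv_z = rpv_z, lpv_z = lpv_z)
}

# Small cached phantoms (generation is deterministic, so caching is safe).
.phantom_cache <- new.env(parent = emptyenv())
cached_case <- function(seed, lesion_count = 0L, straddle = FALSE) {
  key <- paste0("s", seed, "_l", lesion_count, "_st", straddle)
  if (is.null(.phantom_cache[[key]])) {
    cfg <- phantom_config(seed = seed, lesion_count = lesion_count)
    .phantom_cache[[key]] <- generate_case(cfg, straddle = straddle)
  }
  .phantom_cache[[key]]
}

# O(N*M) pure-R surface-distance oracle (independent of the compiled path).
oracle_surface_metrics <- function(X, Y) {
  sx <- unclass(extract_surface(X))
  sy <- unclass(extract_surface(Y))
  dmat <- matrix(0, nrow(sx), nrow(sy))
  for (i in seq_len(nrow(sx))) {
    for (j in seq_len(nrow(sy))) {
      dmat[i, j] <- sqrt(sum((sx[i, ] - sy[j, ])^2))
    }
  }
  rowmin <- apply(dmat, 1, min)
  colmin <- apply(dmat, 2, min)
  list(msd = (sum(rowmin) + sum(colmin)) / (nrow(sx) + nrow(sy)),
       hd = max(max(rowmin), max(colmin)))
}

random_mask_pair <- function(n = 12L, spacing = c(1, 1.3, 2)) {
  repeat {
    a <- array(runif(n^3) < 0.25, c(n, n, n))
    b <- array(runif(n^3) < 0.25, c(n, n, n))
    if (any(a) && any(b)) break
  }
  list(X = vol_grid(a * 1, spacing), Y = vol_grid(b * 1, spacing))
}

# Independent per-voxel Couinaud labeling oracle: explicit loop over voxels
# evaluating each signed distance from the plane definitions directly.
oracle_couinaud_labels <- function(liver_mask, landmarks) {
  planes <- build_separating_planes(landmarks, liver_mask)
  s1 <- suppressWarnings(caudate_region(landmarks, liver_mask))
  d <- dim(liver_mask$data)
  orient <- function(p, axis) {
    n <- p$normal
    if (n[axis] < 0) -n else n
  }
  n_mid <- orient(planes$MID, 1)
  n_rhv <- orient(planes$RHV, 2)
  n_lhv <- orient(planes$LHV_LLF, 1)
  out <- array(0L, d)
  for (lin in which(liver_mask$data > 0)) {
    ijk <- arrayInd(lin, d)
    p <- liver_mask$origin + (as.numeric(ijk) - 1) * liver_mask$spacing
    if (s1$data[lin] > 0) {
      out[lin] <- 1L
      next
    }
    sd_mid <- sum((p - planes$MID$point) * n_mid)
    sd_rhv <- sum((p - planes$RHV$point) * n_rhv)
    sd_lhv <- sum((p - planes$LHV_LLF$point) * n_lhv)
    z <- p[3]
    out[lin] <- if (sd_mid <= 0) {
      if (sd_lhv <= 0) {
        if (z >= planes$LPV_H$point[3]) 2L else 3L
      } else 4L
    } else {
      if (z <= planes$RPV_H$point[3]) {
        if (sd_rhv >= 0) 5L else 6L
      } else {
        if (sd_rhv > 0) 8L else 7L
      }
    }
  }
  out
}

# Relabel a phantom after rigidly translating one vertical divider plane
# along its role-oriented normal by delta mm.
translate_divider <- function(case, role, delta_mm) {
  planes <- build_separating_planes(case$landmarks, case$liver_mask)
  n <- couinaud3d:::role_oriented_normal(planes[[role]])
  planes[[role]]$point <- planes[[role]]$point + delta_mm * n
  assign_couinaud_labels(case$liver_mask, case$landmarks, planes = planes)
}

mean_foreground_dsc <- function(pred, ref) {
  mean(vapply(1:8, function(l) {
    dsc(couinaud3d:::binary_region(pred, l),
        couinaud3d:::binary_region(ref, l))
  }, 0)) / 100
}
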