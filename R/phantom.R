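#' Configuration for synthetic liver phantoms
#'
#' Defines the geometry, intensity and noise regime of a synthetic
#' portal-venous-phase liver MR phantom. Defaults emulate a clinical PVP
#' acquisition: anisotropic spacing (2 x 2 x 3 mm on a 96 x 96 x 64 grid,
#' i.e. a 192 mm field of view), a liver-sized smooth ellipsoid, bright
#' tubular vessels, moderate Gaussian noise and a gentle multiplicative
#' bias field.
#'
#' @param grid_shape integer length-3, voxels per axis.
#' @param spacing_mm numeric length-3, voxel size in mm.
#' @param liver_radius_mm base ellipsoid semi-axes (mm).
#' @param shape_irregularity amplitude of the smooth radial perturbation,
#'   in `[0, 1]` (fraction of the local radius).
#' @param vessel_radius_mm tube radius used when rasterizing vessels.
#' @param lesion_count number of focal lesions to insert (>= 0).
#' @param lesion_diameter_range_mm min/max lesion diameter (mm).
#' @param noise_sigma additive Gaussian noise standard deviation
#'   (arbitrary intensity units).
#' @param bias_field_amplitude relative amplitude of the multiplicative
#'   bias field, in `[0, 1)`.
#' @param seed integer; all phantom randomness derives from it.
#' @return a validated `phantom_config` list.
#' @export
phantom_config <- function(grid_shape = c(96L, 96L, 64L),
                           spacing_mm = c(2, 2, 3),
                           liver_radius_mm = c(70, 55, 65),
                           shape_irregularity = 0.15,
                           vessel_radius_mm = 3,
                           lesion_count = 0L,
                           lesion_diameter_range_mm = c(6, 30),
                           noise_sigma = 5,
                           bias_field_amplitude = 0.15,
                           seed = 1L) {
  cfg <- list(grid_shape = as.integer(grid_shape),
              spacing_mm = as.numeric(spacing_mm),
              liver_radius_mm = as.numeric(liver_radius_mm),
              shape_irregularity = shape_irregularity,
              vessel_radius_mm = vessel_radius_mm,
              lesion_count = as.integer(lesion_count),
              lesion_diameter_range_mm = as.numeric(lesion_diameter_range_mm),
              noise_sigma = noise_sigma,
              bias_field_amplitude = bias_field_amplitude,
              seed = as.integer(seed))
  class(cfg) <- "phantom_config"
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  stopifnot(length(cfg$grid_shape) == 3L, all(cfg$grid_shape >= 8L),
            all(cfg$spacing_mm > 0), all(cfg$liver_radius_mm > 0),
            cfg$shape_irregularity >= 0, cfg$shape_irregularity <= 1,
            cfg$vessel_radius_mm > 0, cfg$lesion_count >= 0L,
            length(cfg$lesion_diameter_range_mm) == 2L,
            all(cfg$lesion_diameter_range_mm > 0),
            cfg$lesion_diameter_range_mm[1] <= cfg$lesion_diameter_range_mm[2],
            cfg$noise_sigma >= 0,
            cfg$bias_field_amplitude >= 0, cfg$bias_field_amplitude < 1)
  # liver (at maximal perturbation plus centre jitter) must fit with a
  # margin of at least 2 voxels on every axis
  half_extent <- (cfg$grid_shape - 1) * cfg$spacing_mm / 2
  max_r <- cfg$liver_radius_mm * (1 + cfg$shape_irregularity) + 4
  if (any(max_r > half_extent - 2 * cfg$spacing_mm)) {
    stop("configuration error: liver does not fit in the grid with a ",
         "2-voxel margin")
  }
  invisible(cfg)
}

phantom_center_mm <- function(cfg) (cfg$grid_shape - 1) * cfg$spacing_mm / 2

# smooth radial modulation on the unit sphere; low-order harmonics only,
# normalized to [-1, 1]
radial_perturbation <- function(theta, phi, coef) {
  raw <- coef[1] * sin(theta) * cos(phi) * cos(theta) +
    coef[2] * sin(theta) * sin(phi) * cos(theta) +
    coef[3] * (3 * cos(theta)^2 - 1) / 2 +
    coef[4] * sin(theta)^2 * cos(2 * phi) +
    coef[5] * sin(theta)^2 * sin(2 * phi) +
    coef[6] * sin(theta)^3 * cos(3 * phi)
  raw / max(sum(abs(coef)), 1e-12)
}

#' Generate a smooth, connected liver mask
#'
#' The liver is an ellipsoid (semi-axes `liver_radius_mm`) whose radius is
#' modulated by a smooth low-order angular perturbation of amplitude
#' `shape_irregularity`, with a small seeded centre jitter. The result is a
#' single connected, smooth region.
#'
#' @param config a [phantom_config()].
#' @return binary [vol_grid()].
#' @export
generate_liver_mask <- function(config) {
  validate_phantom_config(config)
  with_seed(config$seed * 131L + 1L, {
    ctr <- phantom_center_mm(config) + runif(3, -4, 4)
    coef <- rnorm(6)
    vg <- vol_grid(array(0, config$grid_shape), config$spacing_mm)
    pts <- voxel_coords_mm(vg)
    u <- sweep(sweep(pts, 2, ctr), 2, config$liver_radius_mm, `/`)
    rho <- sqrt(rowSums(u^2))
    inside <- rho <= 1e-9
    nz <- which(!inside & rho > 0)
    theta <- acos(pmin(1, pmax(-1, u[nz, 3] / rho[nz])))
    phi <- atan2(u[nz, 2], u[nz, 1])
    rad <- 1 + config$shape_irregularity *
      radial_perturbation(theta, phi, coef)
    inside[nz] <- rho[nz] <= rad
    vg$data <- array(as.numeric(inside), config$grid_shape)
    attr(vg, "center_mm") <- ctr
    vg
  })
}

# distance (mm) from p0 along unit direction dir to the mask boundary
dist_to_surface <- function(mask, p0, dir, step = 1.5, max_mm = 400) {
  tt <- seq(0, max_mm, by = step)
  pts <- outer(tt, dir) + matrix(p0, length(tt), 3, byrow = TRUE)
  idx <- world_to_index(mask, pts)
  d <- dim(mask$data)
  ok <- idx[, 1] >= 1 & idx[, 1] <= d[1] & idx[, 2] >= 1 & idx[, 2] <= d[2] &
    idx[, 3] >= 1 & idx[, 3] <= d[3]
  inside <- ok
  inside[ok] <- mask$data[idx[ok, , drop = FALSE]] > 0
  first_out <- which(!inside)[1]
  if (is.na(first_out)) max_mm else tt[max(first_out - 1L, 1L)]
}

project_onto_plane <- function(p, anchor, normal) {
  p - sum((p - anchor) * normal) * normal
}

keep_inside <- function(pts, mask) {
  idx <- world_to_index(mask, pts)
  d <- dim(mask$data)
  ok <- idx[, 1] >= 1 & idx[, 1] <= d[1] & idx[, 2] >= 1 & idx[, 2] <= d[2] &
    idx[, 3] >= 1 & idx[, 3] <= d[3]
  ok[ok] <- mask$data[idx[ok, , drop = FALSE]] > 0
  pts[ok, , drop = FALSE]
}

#' Construct a landmark set
#'
#' @param IVC,MHV,RHV,LHV,LLF,VL_fissure polylines (n x 3 mm matrices,
#'   n >= 2).
#' @param GB_vertex,RPV,LPV_sag single mm points (length 3); the z
#'   components of `RPV` and `LPV_sag` are the two portal axial levels.
#' @param ivc_radius_mm radius of the IVC tube (mm).
#' @return a `landmark_set`.
#' @export
landmark_set <- function(IVC, MHV, RHV, LHV, LLF, GB_vertex, RPV, LPV_sag,
                         VL_fissure, ivc_radius_mm = 8) {
  polys <- list(IVC = IVC, MHV = MHV, RHV = RHV, LHV = LHV, LLF = LLF,
                VL_fissure = VL_fissure)
  for (nm in names(polys)) {
    p <- polys[[nm]]
    if (!is.matrix(p) || ncol(p) != 3 || nrow(p) < 2) {
      stop("landmark error: ", nm, " must be a polyline with >= 2 points")
    }
  }
  stopifnot(length(GB_vertex) == 3, length(RPV) == 3, length(LPV_sag) == 3)
  structure(c(polys[c("IVC", "MHV", "RHV", "LHV", "LLF")],
              list(GB_vertex = as.numeric(GB_vertex), RPV = as.numeric(RPV),
                   LPV_sag = as.numeric(LPV_sag),
                   VL_fissure = VL_fissure,
                   ivc_radius_mm = ivc_radius_mm)),
            class = "landmark_set")
}

#' Generate anatomical landmarks for a phantom liver
#'
#' Produces an idealized but anatomically arranged landmark set: a vertical
#' IVC centreline at the posterior midline; middle/right/left hepatic-vein
#' polylines radiating from the IVC midpoint inside three vertical planes
#' with seeded obliquity; the left longitudinal fissure continuing the LHV
#' divider inferiorly; a gallbladder-fossa vertex on the infero-anterior
#' liver surface in the MID plane; right-portal and sagittal left-portal
#' points fixing the two horizontal levels; and a venous-ligament fissure
#' curve left-anterior of the IVC delimiting the caudate.
#'
#' @param config a [phantom_config()].
#' @param liver_mask binary [vol_grid()] from [generate_liver_mask()].
#' @return a [landmark_set()].
#' @export
generate_landmarks <- function(config, liver_mask) {
  if (!any(liver_mask$data > 0)) stop("liver mask is empty")
  with_seed(config$seed * 131L + 2L, {
    d <- dim(liver_mask$data)
    idx <- arrayInd(which(liver_mask$data > 0), d)
    pts <- voxel_coords_mm(liver_mask, idx)
    ctr <- colMeans(pts)
    ext <- apply(pts, 2, function(v) diff(range(v)) / 2)
    zr <- range(pts[, 3])

    x_ivc <- ctr[1] - 0.18 * ext[1] + runif(1, -3, 3)
    y_ivc <- ctr[2] - 0.55 * ext[2]
    ivc_z <- seq(zr[1] + 6, zr[2] - 3, length.out = 8)
    IVC <- cbind(x_ivc, y_ivc, ivc_z)
    P0 <- c(x_ivc, y_ivc, ctr[3])

    # vertical divider orientations (degrees from +x about z)
    a_mid <- (-15 + runif(1, -8, 8)) * pi / 180
    a_lhv <- a_mid + runif(1, -5, 5) * pi / 180
    a_rhv <- (115 + runif(1, -8, 8)) * pi / 180
    n_mid <- c(cos(a_mid), sin(a_mid), 0)
    n_lhv <- c(cos(a_lhv), sin(a_lhv), 0)
    n_rhv <- c(cos(a_rhv), sin(a_rhv), 0)

    rpv_z <- ctr[3] - 8 + runif(1, -9, 9)
    lpv_z <- ctr[3] + 2 + runif(1, -9, 9)

    # MID plane: MHV polyline + gallbladder vertex, both in the plane
    inplane_h <- function(n) {             # horizontal in-plane direction
      v <- c(n[2], -n[1], 0)
      v / sqrt(sum(v^2))
    }
    a_dir <- inplane_h(n_mid)
    if (a_dir[2] < 0) a_dir <- -a_dir      # point anterior
    g_dir <- 0.6 * a_dir + c(0, 0, -0.8)
    g_dir <- g_dir / sqrt(sum(g_dir^2))
    GB <- P0 + (dist_to_surface(liver_mask, P0, g_dir) ) * g_dir
    La <- 0.8 * dist_to_surface(liver_mask, P0, a_dir)
    tt <- seq(0.15, 0.8, length.out = 5)
    MHV <- keep_inside(
      t(vapply(tt, function(t) P0 + t * La * a_dir - t * 18 * c(0, 0, 1),
               numeric(3))), liver_mask)

    # RHV plane through the IVC midpoint
    r_dir <- inplane_h(n_rhv)
    if (r_dir[1] < 0) r_dir <- -r_dir      # point right
    Lr <- 0.85 * dist_to_surface(liver_mask, P0, r_dir)
    RHV <- keep_inside(
      t(vapply(seq(0.2, 0.85, length.out = 5),
               function(t) P0 + t * Lr * r_dir - t * 8 * c(0, 0, 1),
               numeric(3))), liver_mask)

    # LHV/LLF divider: a parallel plane anchored left of the MID plane
    Ql <- P0 - (0.24 * ext[1]) * c(1, 0, 0) + c(0, 0.25 * ext[2], 0)
    l_dir <- inplane_h(n_lhv)
    if (l_dir[1] > 0) l_dir <- -l_dir      # point left
    lhv_z <- seq(lpv_z + 6, min(zr[2] - 8, lpv_z + 34), length.out = 4)
    LHV <- keep_inside(t(vapply(seq_along(lhv_z), function(i) {
      p <- project_onto_plane(c(ctr[1], ctr[2] + 6, lhv_z[i]), Ql, n_lhv)
      p + (i - 1) * 6 * l_dir
    }, numeric(3))), liver_mask)
    llf_z <- seq(max(zr[1] + 9, lpv_z - 32), lpv_z - 6, length.out = 4)
    LLF <- keep_inside(t(vapply(llf_z, function(z) {
      project_onto_plane(c(ctr[1], ctr[2] + 0.30 * ext[2], z), Ql, n_lhv)
    }, numeric(3))), liver_mask)

    RPV <- c(ctr[1] + 0.35 * ext[1], ctr[2], rpv_z)
    LPV_sag <- c(ctr[1] - 0.30 * ext[1], ctr[2] + 0.15 * ext[2], lpv_z)

    vl_z <- seq(ctr[3] - 2, min(zr[2] - 9, ctr[3] + 32), length.out = 4)
    VL <- cbind(x_ivc - 28 + 4 * sin(seq(0, pi, length.out = 4)),
                y_ivc + 12, vl_z)

    landmark_set(IVC = IVC, MHV = MHV, RHV = RHV, LHV = LHV, LLF = LLF,
                 GB_vertex = GB, RPV = RPV, LPV_sag = LPV_sag,
                 VL_fissure = VL)
  })
}

sphere_voxels <- function(grid, center_mm, diameter_mm) {
  r <- diameter_mm / 2
  lo <- world_to_index(grid, matrix(center_mm - r, 1))
  hi <- world_to_index(grid, matrix(center_mm + r, 1))
  d <- dim(grid$data)
  lo <- pmax(as.integer(lo), 1L)
  hi <- pmin(as.integer(hi), d)
  if (any(lo > hi)) return(integer(0))
  ii <- as.matrix(expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2],
                              z = lo[3]:hi[3]))
  pp <- voxel_coords_mm(grid, ii)
  keep <- rowSums(sweep(pp, 2, center_mm)^2) <= r^2
  ii <- ii[keep, , drop = FALSE]
  ii[, 1] + d[1] * (ii[, 2] - 1L) + d[1] * d[2] * (ii[, 3] - 1L)
}

new_lesion <- function(id, center_mm, diameter_mm, voxels, labels, type) {
  true_seg <- sort(unique(labels[labels > 0]))
  structure(list(id = id, center_mm = center_mm, diameter_mm = diameter_mm,
                 voxels = voxels, true_segments = true_seg,
                 assigned_segments = NULL, type = type),
            class = "lesion")
}

#' Place a single spherical lesion at a known position
#'
#' Utility for constructing lesions with controlled geometry; records the
#' true segment set as every label its voxels overlap.
#'
#' @param labels a [label_map()].
#' @param center_mm lesion centre (mm).
#' @param diameter_mm lesion diameter (mm).
#' @param id lesion identifier.
#' @param type `"hypo"` or `"hyper"`.
#' @return a `lesion` object.
#' @export
place_lesion <- function(labels, center_mm, diameter_mm, id = 1L,
                         type = "hypo") {
  vox <- sphere_voxels(labels, center_mm, diameter_mm)
  new_lesion(id, center_mm, diameter_mm, vox, labels$data[vox], type)
}

#' Insert random spherical lesions into a labeled phantom liver
#'
#' Lesions are spheres with diameters drawn from the configured range.
#' By default each lesion is placed wholly inside a single segment (its
#' sphere does not touch another label or the liver surface); with
#' `straddle = TRUE` each lesion is centred on an inter-segment boundary so
#' that it deliberately spans two segments, each holding at least 20% of
#' its voxels.
#'
#' @param liver_mask binary [vol_grid()].
#' @param labels the [label_map()] for the same grid.
#' @param config a [phantom_config()] (uses `lesion_count`,
#'   `lesion_diameter_range_mm`, `seed`).
#' @param straddle logical; centre lesions on segment boundaries.
#' @return list of `lesion` objects.
#' @export
insert_lesions <- function(liver_mask, labels, config, straddle = FALSE) {
  n <- config$lesion_count
  if (n == 0L) return(list())
  with_seed(config$seed * 131L + 3L, {
    d <- dim(labels$data)
    liver_lin <- which(liver_mask$data > 0)
    boundary_lin <- which(segment_boundary_mask(labels))
    lesions <- vector("list", n)
    occupied <- integer(0)
    for (i in seq_len(n)) {
      dia <- runif(1, config$lesion_diameter_range_mm[1],
                   config$lesion_diameter_range_mm[2])
      type <- if (runif(1) < 0.7) "hypo" else "hyper"
      placed <- FALSE
      for (try in seq_len(300L)) {
        pool <- if (straddle) boundary_lin else liver_lin
        ctr_lin <- pool[sample.int(length(pool), 1L)]
        ctr <- drop(voxel_coords_mm(labels, arrayInd(ctr_lin, d)))
        vox <- sphere_voxels(labels, ctr, dia)
        if (!length(vox) || length(intersect(vox, occupied))) next
        lv <- labels$data[vox]
        if (any(lv == 0L)) next                      # must stay inside liver
        tab <- table(lv)
        if (straddle) {
          if (length(tab) != 2L || min(tab) / length(lv) < 0.2) next
        } else {
          if (length(tab) != 1L) next
        }
        lesions[[i]] <- new_lesion(i, ctr, dia, vox, lv, type)
        occupied <- c(occupied, vox)
        placed <- TRUE
        break
      }
      if (!placed) {
        stop("placement error: could not place lesion ", i,
             " inside the liver after bounded retries")
      }
    }
    lesions
  })
}

# voxels adjacent (6-connectivity) to a different nonzero label
segment_boundary_mask <- function(labels) {
  a <- labels$data
  d <- dim(a)
  out <- array(FALSE, d)
  cmp <- function(sl_a, sl_b) {
    (sl_a > 0L) & (sl_b > 0L) & (sl_a != sl_b)
  }
  out[-d[1], , ] <- out[-d[1], , ] | cmp(a[-d[1], , ], a[-1, , ])
  out[-1, , ] <- out[-1, , ] | cmp(a[-1, , ], a[-d[1], , ])
  out[, -d[2], ] <- out[, -d[2], ] | cmp(a[, -d[2], ], a[, -1, ])
  out[, -1, ] <- out[, -1, ] | cmp(a[, -1, ], a[, -d[2], ])
  out[, , -d[3]] <- out[, , -d[3]] | cmp(a[, , -d[3]], a[, , -1])
  out[, , -1] <- out[, , -1] | cmp(a[, , -1], a[, , -d[3]])
  out
}

rasterize_tube <- function(canvas, grid, poly, radius_mm, value) {
  # densify the polyline to ~1 mm steps, then paint spheres
  for (s in seq_len(nrow(poly) - 1L)) {
    a <- poly[s, ]; b <- poly[s + 1L, ]
    nstep <- max(2L, ceiling(sqrt(sum((b - a)^2))))
    for (t in seq(0, 1, length.out = nstep)) {
      vox <- sphere_voxels(grid, a + t * (b - a), 2 * radius_mm)
      canvas[vox] <- value
    }
  }
  canvas
}

#' Render phantom intensities
#'
#' Paints the PVP-like piecewise-constant scene (background 40, parenchyma
#' 100, vessels 160, hypo-/hyper-intense lesions 60/150), multiplies by a
#' smooth seeded bias field of relative amplitude
#' `bias_field_amplitude`, and adds Gaussian noise with sd `noise_sigma`.
#'
#' @param liver_mask binary [vol_grid()].
#' @param landmarks a [landmark_set()]; its vessel polylines are rasterized
#'   as bright tubes of radius `vessel_radius_mm`.
#' @param lesions list of `lesion` objects (possibly empty).
#' @param config a [phantom_config()].
#' @return a [vol_grid()] image.
#' @export
render_intensities <- function(liver_mask, landmarks, lesions, config) {
  with_seed(config$seed * 131L + 4L, {
    levels <- c(background = 40, parenchyma = 100, vessel = 160,
                hypo = 60, hyper = 150)
    img <- array(levels["background"], dim(liver_mask$data))
    img[liver_mask$data > 0] <- levels["parenchyma"]
    grid <- vol_grid(img, liver_mask$spacing, liver_mask$origin)
    for (nm in c("IVC", "MHV", "RHV", "LHV")) {
      img <- rasterize_tube(img, grid, landmarks[[nm]],
                            config$vessel_radius_mm, levels["vessel"])
    }
    # short portal stubs at the two horizontal levels
    rpv_seg <- rbind(landmarks$RPV + c(-18, 0, 0), landmarks$RPV + c(18, 0, 0))
    lpv_seg <- rbind(landmarks$LPV_sag + c(0, -14, 0),
                     landmarks$LPV_sag + c(0, 14, 0))
    img <- rasterize_tube(img, grid, rpv_seg, config$vessel_radius_mm,
                          levels["vessel"])
    img <- rasterize_tube(img, grid, lpv_seg, config$vessel_radius_mm,
                          levels["vessel"])
    for (les in lesions) {
      img[les$voxels] <- levels[[les$type]]
    }
    if (config$bias_field_amplitude > 0) {
      ph <- runif(3, 0, 2 * pi)
      ax <- lapply(1:3, function(k) {
        co <- axis_coords_mm(grid, k)
        cos(pi * co / max(co) + ph[k])
      })
      bias <- 1 + config$bias_field_amplitude *
        outer(outer(ax[[1]], ax[[2]]), ax[[3]])
      img <- img * bias
    }
    if (config$noise_sigma > 0) {
      img <- img + array(rnorm(length(img), 0, config$noise_sigma), dim(img))
    }
    vol_grid(img, liver_mask$spacing, liver_mask$origin)
  })
}

#' Generate a complete phantom case
#'
#' Orchestrates mask, landmarks, Couinaud ground-truth labels, lesions and
#' intensity rendering into one deterministic, seed-reproducible case.
#'
#' @param config a [phantom_config()].
#' @param straddle logical; passed to [insert_lesions()].
#' @return a `phantom_case`: list with `image`, `liver_mask`, `labels`,
#'   `landmarks`, `lesions`, `config`.
#' @export
generate_case <- function(config, straddle = FALSE) {
  mask <- generate_liver_mask(config)
  lm <- generate_landmarks(config, mask)
  labels <- assign_couinaud_labels(mask, lm)
  lesions <- insert_lesions(mask, labels, config, straddle = straddle)
  image <- render_intensities(mask, lm, lesions, config)
  structure(list(image = image, liver_mask = mask, labels = labels,
                 landmarks = lm, lesions = lesions, config = config),
            class = "phantom_case")
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case> seed %d, %s voxels, %d lesions\n",
              x$config$seed, paste(dim(x$image$data), collapse = "x"),
              length(x$lesions)))
  invisible(x)
}
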