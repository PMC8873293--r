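test_that("fit_plane recovers exact planes with the stated orientation", {
  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  pl <- fit_plane(pts)
  expect_equal(abs(pl$normal), c(0, 0, 1), tolerance = 1e-12)
  expect_gte(pl$normal[3], 0)  # first nonzero component positive
  expect_equal(max(abs(signed_distance(pts, pl))), 0, tolerance = 1e-12)
})

test_that("fit_plane is a total-least-squares fit under noise", {
  set.seed(11)
  pts <- cbind(5 + rnorm(100, 0, 0.1), runif(100, -10, 10),
               runif(100, -10, 10))
  pl <- fit_plane(pts)
  expect_equal(pl$normal[1], 1, tolerance = 1e-3)
  # plane passes within 0.05 mm of x = 5 at the centroid
  expect_lt(abs(pl$point[1] - 5), 0.05)
})

test_that("degenerate point sets are rejected", {
  expect_error(fit_plane(rbind(c(0, 0, 0), c(1, 1, 1))), "3 points")
  line <- cbind(seq(0, 5, length.out = 10), 0, 0)
  expect_error(fit_plane(line), "collinear")
})

test_that("signed distance follows the normal with batch consistency", {
  pl <- fit_plane(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  expect_equal(signed_distance(c(0.3, -0.2, 0), pl), 0)
  expect_equal(signed_distance(pl$point + 3 * pl$normal, pl), 3)
  set.seed(4)
  pts <- matrix(rnorm(30), 10, 3)
  batch <- signed_distance(pts, pl)
  loop <- vapply(seq_len(10), function(i) signed_distance(pts[i, ], pl), 0)
  expect_equal(batch, loop)
})

test_that("axis-aligned landmarks yield axis-aligned separating planes", {
  fx <- cube_fixture()
  planes <- build_separating_planes(fx$landmarks, fx$mask)
  ang <- function(n, ref) acos(min(1, abs(sum(n * ref)))) * 180 / pi
  expect_lt(ang(planes$MID$normal, c(1, 0, 0)), 1)
  expect_lt(ang(planes$LHV_LLF$normal, c(1, 0, 0)), 1)
  expect_lt(ang(planes$RHV$normal, c(0, 1, 0)), 1)
  expect_equal(planes$RPV_H$normal, c(0, 0, 1))
  expect_equal(planes$LPV_H$normal, c(0, 0, 1))
  expect_equal(planes$RPV_H$point[3], fx$rpv_z)
})

test_that("missing landmarks raise a landmark error", {
  fx <- cube_fixture()
  lm <- fx$landmarks
  lm$GB_vertex <- NULL
  expect_error(build_separating_planes(lm, fx$mask), "GB_vertex")
})

test_that("perturbing the gallbladder vertex tilts only the MID plane", {
  fx <- cube_fixture()
  p0 <- build_separating_planes(fx$landmarks, fx$mask)
  lm <- fx$landmarks
  lm$GB_vertex <- lm$GB_vertex + c(10, 0, 0)
  p1 <- build_separating_planes(lm, fx$mask)
  expect_gt(sum(abs(p1$MID$normal - p0$MID$normal)), 1e-4)
  expect_equal(p1$RHV$normal, p0$RHV$normal)
  expect_equal(p1$LHV_LLF$normal, p0$LHV_LLF$normal)
  expect_equal(p1$RPV_H$point, p0$RPV_H$point)
})

test_that("cube liver with midline planes splits into exact octants", {
  fx <- cube_fixture(n = 20L)
  lab <- assign_couinaud_labels(fx$mask, fx$landmarks)
  counts <- tabulate(lab$data[lab$data > 0], 8)
  expect_equal(counts[1], 0)          # caudate placed outside: no S1
  # brute-force octant classification of the 20^3 cube
  d <- dim(fx$mask$data)
  octant <- array(0L, d)
  for (lin in seq_len(prod(d))) {
    ijk <- arrayInd(lin, d)
    x <- ijk[1] - 1; y <- ijk[2] - 1; z <- ijk[3] - 1
    octant[lin] <- if (x <= fx$mid_x) {
      if (x <= fx$lhv_x) {
        if (z >= fx$lpv_z) 2L else 3L
      } else 4L
    } else {
      if (z <= fx$rpv_z) {
        if (y >= fx$rhv_y) 5L else 6L
      } else {
        if (y > fx$rhv_y) 8L else 7L
      }
    }
  }
  expect_equal(tabulate(octant, 8), counts)
  expect_equal(array(lab$data, d), octant)
})

test_that("a voxel right of MID, posterior of RHV, above RPV_H gets S7", {
  fx <- cube_fixture(n = 20L)
  lab <- assign_couinaud_labels(fx$mask, fx$landmarks)
  # pick a voxel clearly in that octant (0-based world coords = index - 1)
  expect_equal(lab$data[18, 3, 18], 7L)
})

test_that("phantom labels match the per-voxel signed-distance oracle", {
  # small grids keep the explicit per-voxel loop affordable
  for (seed in c(2, 9)) {
    cfg <- phantom_config(grid_shape = c(32L, 32L, 24L),
                          spacing_mm = c(6, 6, 8),
                          liver_radius_mm = c(60, 48, 55), seed = seed)
    mask <- generate_liver_mask(cfg)
    lm <- generate_landmarks(cfg, mask)
    lab <- assign_couinaud_labels(mask, lm)
    expect_equal(array(lab$data, dim(lab$data)),
                 oracle_couinaud_labels(mask, lm))
  }
})

test_that("caudate region is anatomically small and axially bounded", {
  case <- cached_case(5)
  s1 <- caudate_region(case$landmarks, case$liver_mask)
  frac <- sum(s1$data) / sum(case$liver_mask$data)
  expect_gt(frac, 0.005)
  expect_lt(frac, 0.06)
  zr <- range(case$landmarks$VL_fissure[, 3])
  zvox <- which(apply(s1$data, 3, sum) > 0)
  zmm <- axis_coords_mm(s1, 3)[zvox]
  expect_true(all(zmm >= zr[1] - 1e-9 & zmm <= zr[2] + 1e-9))
})

test_that("a displaced venous-ligament fissure gives an empty caudate", {
  case <- cached_case(5)
  lm <- case$landmarks
  lm$VL_fissure <- lm$VL_fissure + matrix(c(0, 0, 500),
                                          nrow(lm$VL_fissure), 3,
                                          byrow = TRUE)
  expect_warning(s1 <- caudate_region(lm, case$liver_mask), "empty")
  expect_equal(sum(s1$data), 0)
})

test_that("labels partition the liver mask exactly", {
  for (seed in c(3, 14)) {
    case <- cached_case(seed)
    lab <- case$labels$data
    liver <- case$liver_mask$data > 0
    expect_true(all(lab[liver] >= 1L & lab[liver] <= 8L))
    expect_true(all(lab[!liver] == 0L))
    expect_equal(sum(tabulate(lab[liver], 8)), sum(liver))
  }
})

test_that("superior/inferior splits respect the portal levels", {
  case <- cached_case(3)
  planes <- build_separating_planes(case$landmarks, case$liver_mask)
  lab <- case$labels
  d <- dim(lab$data)
  z <- axis_coords_mm(lab, 3)[arrayInd(seq_along(lab$data), d)[, 3]]
  expect_true(all(z[lab$data == 2L] >= planes$LPV_H$point[3]))
  expect_true(all(z[lab$data == 3L] < planes$LPV_H$point[3]))
  expect_true(all(z[lab$data == 8L] > planes$RPV_H$point[3]))
  expect_true(all(z[lab$data == 5L] <= planes$RPV_H$point[3]))
  expect_true(all(z[lab$data == 7L] > planes$RPV_H$point[3]))
  expect_true(all(z[lab$data == 6L] <= planes$RPV_H$point[3]))
})
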