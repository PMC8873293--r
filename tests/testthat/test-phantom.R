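test_that("config invariants are enforced", {
  expect_error(phantom_config(liver_radius_mm = c(120, 55, 65)),
               "does not fit")
  expect_error(phantom_config(lesion_diameter_range_mm = c(30, 6)))
  expect_error(phantom_config(bias_field_amplitude = 1))
})

test_that("an unperturbed liver is a discretized ellipsoid", {
  cfg <- phantom_config(shape_irregularity = 0, seed = 2)
  m <- generate_liver_mask(cfg)
  analytic <- 4 / 3 * pi * prod(cfg$liver_radius_mm) / voxel_volume_mm3(m)
  # voxel count within one boundary shell of the analytic volume
  surf <- sum(m$data > 0 & !couinaud3d:::erode6(m$data > 0))
  expect_lt(abs(sum(m$data) - analytic), surf)
})

test_that("identical seeds reproduce cases bit-identically", {
  a <- generate_case(phantom_config(seed = 42, lesion_count = 2L))
  b <- generate_case(phantom_config(seed = 42, lesion_count = 2L))
  expect_identical(a$image$data, b$image$data)
  expect_identical(a$labels$data, b$labels$data)
  expect_identical(a$landmarks, b$landmarks)
  expect_identical(lapply(a$lesions, `[[`, "voxels"),
                   lapply(b$lesions, `[[`, "voxels"))
  c2 <- generate_case(phantom_config(seed = 43))
  expect_false(identical(a$image$data, c2$image$data))
})

test_that("masks are single connected components across seeds", {
  for (seed in 1:12) {
    m <- generate_liver_mask(phantom_config(seed = seed))
    cc <- label_components(m$data, 26L)
    expect_equal(max(cc), 1L)
    vol <- sum(m$data) * voxel_volume_mm3(m)
    ell <- 4 / 3 * pi * prod(phantom_config()$liver_radius_mm)
    expect_lt(abs(vol - ell) / ell, 0.3)
  }
})

test_that("vein polylines partition the liver into four nonzero sectors", {
  case <- cached_case(6)
  lab <- case$labels$data
  sectors <- list(lateral = c(2L, 3L), medial = 4L, anterior = c(5L, 8L),
                  posterior = c(6L, 7L))
  for (s in sectors) expect_gt(sum(lab %in% s), 0)
  # plausibility: every segment holds at least 2% of the liver
  frac <- tabulate(lab[lab > 0], 8) / sum(lab > 0)
  expect_true(all(frac >= 0.02))
})

test_that("the gallbladder vertex sits on the liver surface", {
  case <- cached_case(6)
  surf <- extract_surface(case$liver_mask)
  gb <- case$landmarks$GB_vertex
  dmin <- sqrt(min(rowSums(sweep(unclass(surf), 2, gb)^2)))
  expect_lt(dmin, 2 * max(case$liver_mask$spacing))
})

test_that("hepatic-vein polylines start near the IVC midpoint", {
  case <- cached_case(6)
  lm <- case$landmarks
  p0 <- lm$IVC[(nrow(lm$IVC) + 1) %/% 2, ]
  for (nm in c("MHV", "RHV")) {
    d0 <- sqrt(sum((lm[[nm]][1, ] - p0)^2))
    expect_lt(d0, 60)
  }
})

test_that("noiseless rendering is piecewise constant at the set levels", {
  cfg <- phantom_config(noise_sigma = 0, bias_field_amplitude = 0, seed = 3)
  mask <- generate_liver_mask(cfg)
  lmk <- generate_landmarks(cfg, mask)
  img <- render_intensities(mask, lmk, list(), cfg)
  vals <- sort(unique(as.numeric(img$data)))
  expect_setequal(vals, c(40, 100, 160))
  expect_gt(mean(img$data[mask$data > 0]), mean(img$data[mask$data == 0]))
})

test_that("noise has the configured standard deviation", {
  cfg0 <- phantom_config(noise_sigma = 0, bias_field_amplitude = 0, seed = 4)
  cfg1 <- phantom_config(noise_sigma = 10, bias_field_amplitude = 0,
                         seed = 4)
  mask <- generate_liver_mask(cfg0)
  lmk <- generate_landmarks(cfg0, mask)
  base <- render_intensities(mask, lmk, list(), cfg0)
  noisy <- render_intensities(mask, lmk, list(), cfg1)
  resid <- noisy$data - base$data
  expect_gt(length(resid), 1e5)
  expect_lt(abs(sd(resid) - 10), 0.5)
})

test_that("lesion intensities and truth sets follow construction", {
  cfg <- phantom_config(seed = 8, lesion_count = 3L,
                        lesion_diameter_range_mm = c(10, 24),
                        noise_sigma = 0, bias_field_amplitude = 0)
  case <- generate_case(cfg)
  expect_length(case$lesions, 3L)
  for (les in case$lesions) {
    expect_length(les$true_segments, 1L)     # default placement: single
    # brute-force truth: labels overlapped by >= 1 voxel
    expect_equal(les$true_segments,
                 sort(unique(case$labels$data[les$voxels])))
    mu <- mean(case$image$data[les$voxels])
    par_mu <- 100
    if (les$type == "hypo") expect_lt(mu, par_mu) else expect_gt(mu, par_mu)
  }
  expect_equal(insert_lesions(case$liver_mask, case$labels,
                              phantom_config(seed = 8, lesion_count = 0L)),
               list())
})

test_that("straddle placement spans exactly two segments substantially", {
  cfg <- phantom_config(seed = 9, lesion_count = 3L,
                        lesion_diameter_range_mm = c(14, 20))
  case <- generate_case(cfg, straddle = TRUE)
  for (les in case$lesions) {
    expect_length(les$true_segments, 2L)
    tab <- table(case$labels$data[les$voxels])
    expect_gte(min(tab) / length(les$voxels), 0.2)
  }
})

test_that("all eight labels appear in a default case", {
  case <- cached_case(1)
  expect_setequal(sort(unique(case$labels$data[case$labels$data > 0])), 1:8)
})
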