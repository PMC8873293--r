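test_that("shift grading follows the mm and slice thresholds", {
  expect_equal(grade_shift(4, "MID"), "slight")
  expect_equal(grade_shift(5, "RHV"), "slight")
  expect_equal(grade_shift(7, "LHV_LLF"), "moderate")
  expect_equal(grade_shift(10, "MID"), "severe")
  expect_equal(grade_shift(12, "MID"), "severe")
  expect_equal(grade_shift(2, "RPV_H"), "slight")
  expect_equal(grade_shift(3, "LPV_H"), "moderate")
  expect_equal(grade_shift(5, "RPV_H"), "severe")
  expect_error(grade_shift(3, "XXX"), "unknown")
})

test_that("quality classification matches the quoted rules exactly", {
  expect_equal(classify_quality(c("slight", "slight", "none", "none",
                                  "none"), FALSE), "good")
  expect_equal(classify_quality(c("moderate", "none", "none", "none",
                                  "none"), FALSE), "good")
  expect_equal(classify_quality(c("severe", "none", "none", "none", "none"),
                                FALSE), "poor")
  expect_equal(classify_quality(c("slight", "slight", "slight", "none",
                                  "none"), FALSE), "moderate")
  expect_equal(classify_quality(c("moderate", "slight", "none", "none",
                                  "none"), FALSE), "moderate")
  expect_equal(classify_quality(rep("none", 5), TRUE), "poor")
  expect_error(classify_quality(rep("none", 4), FALSE), "five")
  expect_error(classify_quality(c(rep("none", 4), "bad"), FALSE), "unknown")
})

test_that("the rubric decision table is exhaustive and rule-consistent", {
  grades <- c("none", "slight", "moderate", "severe")
  combos <- expand.grid(g1 = grades, g2 = grades, g3 = grades, g4 = grades,
                        g5 = grades, fault = c(FALSE, TRUE),
                        stringsAsFactors = FALSE)
  # independent re-encoding of the three quoted rules
  oracle <- function(g, fault) {
    if (any(g == "severe") || fault) return("poor")
    s <- sum(g == "slight"); m <- sum(g == "moderate")
    good <- (m == 0 && s <= 2) || (m == 1 && s == 0)
    if (good) "good" else "moderate"
  }
  for (i in seq_len(nrow(combos))) {
    g <- unlist(combos[i, 1:5], use.names = FALSE)
    got <- classify_quality(g, combos$fault[i])
    expect_true(got %in% c("good", "moderate", "poor"))
    expect_identical(got, oracle(g, combos$fault[i]))
  }
})

test_that("plane shifts are zero for identical maps", {
  case <- cached_case(3)
  for (role in c("MID", "RHV", "LHV_LLF", "RPV_H", "LPV_H")) {
    expect_equal(measure_plane_shift(case$labels, case$labels, role), 0,
                 tolerance = 1e-9)
  }
})

test_that("a translated RHV divider is measured at its displacement", {
  case <- cached_case(3)
  for (delta in c(4, 8)) {
    pred <- translate_divider(case, "RHV", delta)
    m <- measure_plane_shift(pred, case$labels, "RHV")
    expect_lt(abs(m - delta), max(case$labels$spacing))
  }
})

test_that("a horizontal boundary moved k slices measures k", {
  case <- cached_case(3)
  lm <- case$landmarks
  dz <- 3 * case$labels$spacing[3]
  lm$RPV[3] <- lm$RPV[3] + dz
  pred <- assign_couinaud_labels(case$liver_mask, lm)
  expect_equal(measure_plane_shift(pred, case$labels, "RPV_H"), 3)
})

test_that("missing boundaries are flagged unmeasurable", {
  case <- cached_case(3)
  pred <- case$labels
  pred$data[pred$data == 4L] <- 2L   # removes the LHV_LLF boundary pair
  expect_warning(m <- measure_plane_shift(pred, case$labels, "LHV_LLF"),
                 "unmeasurable")
  expect_equal(m, Inf)
})

test_that("fault detection separates blobs from plane shifts", {
  case <- cached_case(3)
  expect_false(detect_fault(case$labels, case$labels))
  # plane-explainable error: translated divider
  pred <- translate_divider(case, "RHV", 6)
  expect_false(detect_fault(pred, case$labels))
  # a 3 cm blob deep inside a segment relabeled to another segment
  lab7 <- which(case$labels$data == 7L)
  d <- dim(case$labels$data)
  pts <- voxel_coords_mm(case$labels, arrayInd(lab7, d))
  bnd <- couinaud3d:::ref_divider_boundary(case$labels)
  bnd_pts <- voxel_coords_mm(case$labels, arrayInd(bnd, d))
  dmin <- vapply(seq_len(nrow(pts)), function(i) {
    sqrt(min(rowSums(sweep(bnd_pts, 2, pts[i, ])^2)))
  }, 0)
  ctr <- pts[which.max(dmin), ]
  blob <- couinaud3d:::sphere_voxels(case$labels, ctr, 30)
  pred2 <- case$labels
  pred2$data[blob] <- 2L
  expect_true(detect_fault(pred2, case$labels))
})

test_that("quality_report composes shifts, fault and overall class", {
  case <- cached_case(3)
  qr <- quality_report(case$labels, case$labels)
  expect_equal(qr$overall, "good")
  expect_false(qr$fault)
  expect_true(all(qr$shifts$grade == "none"))
  pred <- translate_divider(case, "RHV", 12)
  qr2 <- quality_report(pred, case$labels)
  expect_equal(qr2$shifts$grade[qr2$shifts$plane_role == "RHV"], "severe")
  expect_equal(qr2$overall, "poor")
})

test_that("lesion filtering drops <=5 mm and keeps the five largest", {
  mk <- function(id, dia) {
    structure(list(id = id, center_mm = c(0, 0, 0), diameter_mm = dia,
                   voxels = integer(0), true_segments = 1L,
                   assigned_segments = NULL, type = "hypo"),
              class = "lesion")
  }
  les <- Map(mk, 1:7, c(4, 20, 18, 16, 14, 12, 10))
  kept <- filter_lesions(les)
  expect_length(kept, 5)
  expect_equal(vapply(kept, `[[`, 0, "diameter_mm"), c(20, 18, 16, 14, 12))
  expect_length(filter_lesions(Map(mk, 1:3, c(3, 4, 5))), 0)
  expect_length(filter_lesions(Map(mk, 1:5, c(6, 7, 8, 9, 10))), 5)
  # ties break towards the lower id
  tied <- Map(mk, 1:6, c(10, 10, 10, 10, 10, 10))
  expect_equal(vapply(filter_lesions(tied), `[[`, 0L, "id"), 1:5)
})

test_that("localization follows the 10% rule with modal fallback", {
  case <- cached_case(3)
  lab <- case$labels
  # fully inside S5
  d <- dim(lab$data)
  s5 <- which(lab$data == 5L)
  pts <- voxel_coords_mm(lab, arrayInd(s5, d))
  ctr <- colMeans(pts)
  les <- place_lesion(lab, ctr, 10)
  les <- localize_lesion(les, lab)
  expect_equal(les$assigned_segments, 5L)

  # synthetic 95/5 split across two segments
  fake <- lab
  vox <- les$voxels
  n <- length(vox)
  fake$data[vox] <- 4L
  fake$data[vox[seq_len(ceiling(0.05 * n))]] <- 8L
  l2 <- localize_lesion(les, fake)
  expect_equal(l2$assigned_segments, 4L)
  # a 50/50 straddle keeps both
  fake$data[vox[seq_len(floor(n / 2))]] <- 8L
  l3 <- localize_lesion(les, fake)
  expect_equal(l3$assigned_segments, c(4L, 8L))
  # outside the predicted liver: unlocalizable
  fake$data[vox] <- 0L
  l4 <- localize_lesion(les, fake)
  expect_length(l4$assigned_segments, 0)
})

test_that("weighted kappa matches hand-computed values and bounds", {
  cats <- c("good", "moderate", "poor")
  expect_equal(weighted_kappa(rep(cats, 4), rep(cats, 4), cats), 1)
  # 2-category negation with balanced margins -> -1
  a <- rep(c("good", "poor"), 10)
  b <- rep(c("poor", "good"), 10)
  expect_equal(weighted_kappa(a, b, c("good", "poor")), -1)
  # 3x3 contingency fixture, hand evaluation of the formula
  a3 <- c(rep("good", 6), rep("moderate", 3), rep("poor", 1),
          "good", "moderate")
  b3 <- c(rep("good", 5), "moderate", rep("moderate", 2), "poor",
          "poor", "moderate", "good")
  k <- length(cats)
  W <- abs(outer(1:3, 1:3, `-`)) / 2
  O <- table(factor(a3, cats), factor(b3, cats)) / length(a3)
  E <- outer(as.numeric(table(factor(a3, cats))),
             as.numeric(table(factor(b3, cats)))) / length(a3)^2
  expected <- 1 - sum(W * O) / sum(W * E)
  expect_equal(weighted_kappa(a3, b3, cats), expected)
  expect_gte(expected, -1)
  expect_lte(expected, 1)
  # k = 2 weighted kappa equals unweighted kappa
  set.seed(3)
  x <- sample(c("good", "poor"), 40, TRUE)
  y <- sample(c("good", "poor"), 40, TRUE)
  O2 <- table(factor(x, c("good", "poor")), factor(y, c("good", "poor"))) /
    40
  po <- sum(diag(O2))
  pe <- sum(rowSums(O2) * colSums(O2))
  expect_equal(weighted_kappa(x, y, c("good", "poor")),
               (po - pe) / (1 - pe))
  expect_error(weighted_kappa("good", "good", cats), ">= 2")
  expect_error(weighted_kappa(c("good", "bad"), c("good", "good"), cats),
               "unknown")
})
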