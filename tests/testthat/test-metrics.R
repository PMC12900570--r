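# Overlap and surface-distance metrics against brute-force oracles.

test_that("smoothed DSC and IoU match the printed formulas", {
  e <- array(FALSE, c(3, 3, 3))
  expect_equal(dsc(e, e), 1)                 # (0+1)/(0+1)
  expect_equal(iou(e, e), 1)
  a <- e; a[1:2, 1, 1] <- TRUE               # |GT| = 2
  b <- e; b[2:3, 1, 1] <- TRUE               # |Pred| = 2, overlap 1
  expect_equal(dsc(a, b), 3 / 5)
  expect_equal(iou(a, b), 2 / 4)
  expect_equal(dsc(a, a), 1)
  # symmetry
  expect_equal(dsc(a, b), dsc(b, a))
  expect_equal(iou(a, b), iou(b, a))
  # strict (unsmoothed) flag
  expect_equal(dsc(a, b, smooth = FALSE), 2 * 1 / 4)
  expect_true(is.nan(dsc(e, e, smooth = FALSE)))
  expect_error(dsc(a, array(FALSE, c(3, 3, 2))), "differ")
})

test_that("surface extraction follows 6-connectivity with border = outside", {
  m <- array(FALSE, c(5, 5, 5))
  m[3, 3, 3] <- TRUE
  expect_identical(nrow(surface_voxels(m)), 1L)       # lone voxel
  cube <- array(FALSE, c(5, 5, 5)); cube[2:4, 2:4, 2:4] <- TRUE
  expect_identical(nrow(surface_voxels(cube)), 26L)   # all but the centre
  expect_identical(nrow(surface_voxels(array(FALSE, c(4, 4, 4)))), 0L)
  # a voxel on the volume border is surface even if fully surrounded inside
  full <- array(TRUE, c(3, 3, 3))
  expect_identical(nrow(surface_voxels(full)), 26L)   # centre is interior
})

test_that("hd95/assd reproduce hand values and scale with spacing", {
  a <- array(FALSE, c(1, 1, 5)); a[1, 1, 1] <- TRUE
  b <- array(FALSE, c(1, 1, 5)); b[1, 1, 4] <- TRUE
  expect_equal(hd95(a, b, c(1, 1, 1)), 3)
  expect_equal(assd(a, b, c(1, 1, 1)), 3)              # (3 + 3) / 2
  expect_equal(hd95(a, b, c(1, 1, 2)), 6)              # spacing-scaled
  expect_equal(hd95(a, a, c(1, 1, 1)), 0)
  expect_equal(assd(a, a, c(1, 1, 1)), 0)
  expect_error(hd95(a, array(FALSE, c(1, 1, 5))), "non-empty")
  expect_error(assd(array(FALSE, c(1, 1, 5)), b), "non-empty")
  # asymmetric toy: one point vs two points on a line
  p1 <- array(FALSE, c(1, 1, 6)); p1[1, 1, 2] <- TRUE
  p2 <- array(FALSE, c(1, 1, 6)); p2[1, 1, c(1, 5)] <- TRUE
  # directed: from p1 min(1,3)=1; from p2: 1 and 3
  expect_equal(assd(p1, p2, c(1, 1, 1)), (1 + 1 + 3) / 3)
  expect_equal(hd95(p1, p2, c(1, 1, 1)),
               max(1, quantile(c(1, 3), .95, names = FALSE)))
})

test_that("random masks agree with the brute-force oracles", {
  spacings <- list(c(1, 1, 1), c(4.5, 1, 1), c(2, 0.7, 1.3))
  for (i in 1:8) {
    gt <- rand_mask(8, 0.3, seed = i)
    pred <- rand_mask(8, 0.3, seed = 100 + i)
    sp <- spacings[[1 + (i %% 3)]]
    lin <- function(m) sort((m[, 3] - 1) * 64 + (m[, 2] - 1) * 8 + m[, 1])
    expect_identical(lin(surface_voxels(gt)), lin(oracle_surface(gt)))
    expect_equal(hd95(gt, pred, sp), oracle_hd95(gt, pred, sp),
                 tolerance = 1e-9)
    expect_equal(assd(gt, pred, sp), oracle_assd(gt, pred, sp),
                 tolerance = 1e-9)
    # symmetry of the implementations
    expect_equal(hd95(gt, pred, sp), hd95(pred, gt, sp), tolerance = 1e-12)
    expect_equal(assd(gt, pred, sp), assd(pred, gt, sp), tolerance = 1e-12)
  }
})

test_that("evaluate_case aggregates per class with an unweighted mean", {
  ph <- generate_phantom(phantom_config(shape = c(10, 48, 24), seed = 3))
  m3 <- to_three_class(ph$labels)
  rep_ <- evaluate_case(m3, m3)
  expect_equal(rep_["vertebra", "dsc"], 1)
  expect_equal(rep_["disc", "iou"], 1)
  expect_equal(rep_["vertebra", "hd95"], 0)
  expect_equal(rep_["mean", "assd"], 0)
  # ten-class input collapses to three-class automatically
  rep10 <- evaluate_case(ph$labels, m3)
  expect_equal(rep10["mean", "dsc"], 1)
  # mean row is the unweighted average
  pred <- m3
  pred$labels[pred$labels == 2L][1:10] <- 0L
  r2 <- evaluate_case(m3, pred)
  expect_equal(r2["mean", "dsc"],
               (r2["vertebra", "dsc"] + r2["disc", "dsc"]) / 2)
  # empty prediction for a class -> NA distances, not zero
  none <- m3; none$labels[none$labels == 2L] <- 0L
  r3 <- evaluate_case(m3, none)
  expect_true(is.na(r3["disc", "hd95"]))
  expect_true(is.na(r3["disc", "assd"]))
})
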