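# Phantom generator, label handling, NIfTI round trips, preprocessing and
# augmentation.

test_that("phantom is deterministic, contrast-correct and fully labelled", {
  cfg <- phantom_config(shape = c(16, 64, 32), seed = 7)
  ph1 <- generate_phantom(cfg)
  ph2 <- generate_phantom(cfg)
  expect_identical(ph1$volume$t1, ph2$volume$t1)
  expect_identical(ph1$volume$t2, ph2$volume$t2)
  expect_identical(ph1$labels$labels, ph2$labels$labels)
  ph3 <- generate_phantom(phantom_config(shape = c(16, 64, 32), seed = 8))
  expect_false(identical(ph1$volume$t1, ph3$volume$t1))

  # all ten labels present for 5 vertebrae
  expect_setequal(sort(unique(as.vector(ph1$labels$labels))), 0:9)
  expect_identical(ph1$labels$scheme, "TEN_CLASS")

  # noise-free construction forces the contrast signs exactly
  phc <- generate_phantom(phantom_config(shape = c(16, 64, 32), seed = 1,
                                         noise_sigma = 0, bias_strength = 0))
  lab <- phc$labels$labels
  vert <- lab >= 1 & lab <= 5; disc <- lab >= 6
  expect_gt(mean(phc$volume$t1[vert]), mean(phc$volume$t1[disc]))
  expect_gt(mean(phc$volume$t2[disc]), mean(phc$volume$t2[vert]))
  # noisy default keeps the ordering too
  m3 <- to_three_class(ph1$labels)
  expect_gt(mean(ph1$volume$t1[m3$labels == 1]), mean(ph1$volume$t1[m3$labels == 2]))
  expect_gt(mean(ph1$volume$t2[m3$labels == 2]), mean(ph1$volume$t2[m3$labels == 1]))
})

test_that("noise-free voxel intensities equal base intensity times bias", {
  ph <- generate_phantom(phantom_config(shape = c(12, 48, 24), seed = 3,
                                        noise_sigma = 0, bias_strength = 0.3))
  lab <- ph$labels$labels
  base <- spineseg:::PHANTOM_INTENSITY$t1
  # bias field is shared between modalities: the implied ratio t1/t2 must be
  # the piecewise-constant ratio of base intensities
  vert <- lab == 2
  r <- ph$volume$t1[vert] / ph$volume$t2[vert]
  expect_equal(max(abs(r - base[["vertebra"]] /
                         spineseg:::PHANTOM_INTENSITY$t2[["vertebra"]])), 0,
               tolerance = 1e-12)
  # and the bias-normalized intensity is constant within a structure
  b <- ph$volume$t1[vert] / base[["vertebra"]]
  expect_true(all(b > 0.69 & b < 1.31))
})

test_that("too-small height errors with the minimum named", {
  expect_error(generate_phantom(phantom_config(shape = c(8, 10, 8))),
               "need height >=")
})

test_that("to_three_class maps labels and conserves counts", {
  ph <- generate_phantom(phantom_config(shape = c(12, 64, 32), seed = 2))
  m3 <- to_three_class(ph$labels)
  lab10 <- ph$labels$labels
  expect_identical(sum(m3$labels == 1), sum(lab10 >= 1 & lab10 <= 5))
  expect_identical(sum(m3$labels == 2), sum(lab10 >= 6))
  expect_identical(sum(m3$labels == 0), sum(lab10 == 0))
  expect_error(to_three_class(m3), "already")

  pure7 <- ph$labels
  pure7$labels[] <- 7L
  expect_true(all(to_three_class(pure7)$labels == 2L))
  zero <- ph$labels; zero$labels[] <- 0L
  expect_true(all(to_three_class(zero)$labels == 0L))
})

test_that("NIfTI write/read round trip preserves data, spacing, affine", {
  ph <- generate_phantom(phantom_config(shape = c(10, 48, 24), seed = 5,
                                        spacing = c(4.5, 0.7, 0.7)))
  dir <- file.path(tempdir(), "nifti_rt")
  write_volume(ph$volume, dir, ph$labels)
  r <- read_volume(dir)
  expect_lt(max(abs(r$volume$t1 - ph$volume$t1)), 1e-6)
  expect_lt(max(abs(r$volume$t2 - ph$volume$t2)), 1e-6)
  expect_equal(r$volume$spacing, c(4.5, 0.7, 0.7), tolerance = 1e-6)
  expect_equal(r$volume$affine[1, 1], 4.5, tolerance = 1e-6)
  expect_identical(r$labels$labels, ph$labels$labels)

  expect_error(read_volume(file.path(tempdir(), "nope")), "expected t1")
  # non-3D rejection
  p2d <- file.path(tempdir(), "flat.nii")
  x <- matrix(rnorm(12), 3, 4)
  con <- file(p2d, "wb")
  writeBin(as.integer(348), con, size = 4L, endian = "little")
  writeBin(raw(36), con)
  writeBin(as.integer(c(2, 3, 4, 1, 1, 1, 1, 1)), con, size = 2L,
           endian = "little")
  writeBin(raw(352 - 56), con)
  close(con)
  expect_error(read_nifti(p2d), "3D")
})

test_that("NIfTI header agrees with an independent reader (nibabel)", {
  py <- Sys.which("python")
  skip_if(py == "", "python not on PATH")
  ph <- generate_phantom(phantom_config(shape = c(8, 24, 12), seed = 1))
  f <- file.path(tempdir(), "xcheck.nii.gz")
  write_nifti(ph$volume$t1, f, spacing = c(4.5, 1, 1))
  out <- tryCatch(system2(py, c("-c", shQuote(paste0(
    "import nibabel, numpy; img = nibabel.load('", f, "'); ",
    "print(img.shape); print(tuple(float(round(float(z),3)) for z in img.header.get_zooms())); ",
    "print(round(float(numpy.asarray(img.dataobj).sum()),3))"))),
    stdout = TRUE, stderr = TRUE), warning = function(w) NULL)
  skip_if(is.null(out) || length(out) < 3, "nibabel unavailable")
  expect_identical(out[1], "(8, 24, 12)")
  expect_identical(out[2], "(4.5, 1.0, 1.0)")
  expect_equal(as.numeric(out[3]), sum(ph$volume$t1), tolerance = 1e-2)
})

test_that("preprocess resamples, standardizes and rescales spacing", {
  # clinical-range input size maps to the default 48 x 256 x 256 grid
  vol11 <- structure(list(t1 = array(rnorm(11 * 408 * 489), c(11, 408, 489)),
                          t2 = array(rnorm(11 * 408 * 489), c(11, 408, 489)),
                          spacing = c(4.5, 1, 1), affine = diag(c(4.5, 1, 1, 1))),
                     class = "volume_pair")
  expect_identical(dim(preprocess_volume(vol11)$t1), c(48L, 256L, 256L))

  ph <- generate_phantom(phantom_config(shape = c(11, 96, 89), seed = 4))
  pp <- preprocess_volume(ph$volume, target_depth = 48, target_hw = 64)
  expect_identical(dim(pp$t1), c(48L, 64L, 64L))
  expect_lt(abs(mean(pp$t1)), 1e-4)
  expect_lt(abs(sd(pp$t1) - 1), 1e-4)
  expect_equal(pp$spacing[1], 4.5 * 11 / 48, tolerance = 1e-9)

  # identity when already at target with standardization off
  same <- preprocess_volume(pp, 48, 64, standardize = FALSE)
  expect_equal(same$t1, pp$t1, tolerance = 1e-12)

  bad <- ph$volume; bad$t1 <- array(1, c(1, 4, 4)); bad$t2 <- bad$t1
  expect_error(preprocess_volume(bad), "degenerate")
})

test_that("augmentation is seeded, paired, and label-preserving", {
  ph <- generate_phantom(phantom_config(shape = c(8, 64, 32), seed = 6))
  a1 <- augment_pair(ph$volume, ph$labels, seed = 11)
  a2 <- augment_pair(ph$volume, ph$labels, seed = 11)
  expect_identical(a1$volume$t1, a2$volume$t1)
  expect_identical(a1$labels$labels, a2$labels$labels)
  # identity transform
  id <- augment_pair(ph$volume, ph$labels, seed = 1, max_angle = 0,
                     min_crop = 1)
  expect_equal(id$volume$t1, ph$volume$t1, tolerance = 1e-12)
  expect_identical(id$labels$labels, ph$labels$labels)
  # no label invention under rotation + crop + resize
  expect_true(all(unique(as.vector(a1$labels$labels)) %in%
                    unique(as.vector(ph$labels$labels))))
  expect_identical(dim(a1$volume$t1), dim(ph$volume$t1))
})
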