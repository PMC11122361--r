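# Chromatogram I/O, peak detection, integration and retention-time
# assignment.

test_that("chromatograms validate their invariants", {
  expect_error(chromatogram(c(1, 2, 2), c(0, 1, 0)), "row 3")
  expect_error(chromatogram(c(1, 0), c(0, 1)), "strictly increasing")
  expect_error(chromatogram(1:3, 1:2), "length")
  expect_error(chromatogram(1:3, c(0, 1, 0), detector = "EIC"), "eic_mz")
  x <- chromatogram(1:3, c(0, 5, 0))
  expect_s3_class(x, "chromatogram")
})

test_that("delimited text round-trips a chromatogram at full precision", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  x <- gaussian_chromatogram(c(2.5, 1.2), c(40, 55),
                             t = seq(30, 70, by = 0.05),
                             detector = "TIC", sample_id = "rt1")
  write_chromatogram(x, tmp)
  y <- read_chromatogram(tmp)
  expect_identical(y$times, x$times)
  expect_identical(y$intensities, x$intensities)
  expect_identical(y$detector, "TIC")
  expect_identical(y$sample_id, "rt1")

  # EIC metadata survives
  e <- chromatogram(1:5, c(0, 1, 3, 1, 0), detector = "EIC", eic_mz = 118,
                    sample_id = "e")
  write_chromatogram(e, tmp)
  expect_identical(read_chromatogram(tmp)$eic_mz, 118L)
})

test_that("malformed chromatogram files are rejected with row numbers", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_min,intensity", "1,0", "2,x", "3,0"), tmp)
  expect_error(read_chromatogram(tmp), "row 3")
  writeLines(c("1,0", "2,1", "2,2"), tmp)
  expect_error(read_chromatogram(tmp), "row 3")
  writeLines(character(0), tmp)
  expect_error(read_chromatogram(tmp), "empty")
  # simple 3-row CSV parses
  writeLines(c("0,0", "1,5", "2,0"), tmp)
  expect_equal(read_chromatogram(tmp)$times, c(0, 1, 2))
})

test_that("peak detection finds Gaussian apexes and valley bounds", {
  # single noiseless Gaussian: one peak at its center
  x <- gaussian_chromatogram(1, 50)
  pk <- detect_peaks(x)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$apex_time, 50, tolerance = 1e-6)

  # two Gaussians >= 6 sigma apart: two peaks with the valley between
  x2 <- gaussian_chromatogram(c(1, 1), c(50, 51), sigma = 0.1)
  pk2 <- detect_peaks(x2)
  expect_equal(nrow(pk2), 2L)
  expect_equal(pk2$apex_time, c(50, 51), tolerance = 1e-3)
  expect_true(pk2$right_time[1] >= 50 && pk2$right_time[1] <= 51)
  expect_true(pk2$left_time[2] >= 50 && pk2$left_time[2] <= 51)
  expect_true(all(pk2$left_time < pk2$apex_time))
  expect_true(all(pk2$apex_time <= pk2$right_time))

  # flat traces yield an empty table
  flat <- chromatogram(seq(0, 10, 0.1), rep(0, 101))
  expect_equal(nrow(detect_peaks(flat)), 0L)

  # halfwidth clips the bounds
  pk3 <- detect_peaks(x, halfwidth = 0.25)
  expect_equal(pk3$left_time, pk3$apex_time - 0.25, tolerance = 1e-9)
})

test_that("trapezoidal integration matches analytic Gaussian areas", {
  x <- gaussian_chromatogram(1, 50)
  pk <- detect_peaks(x)
  area <- integrate_peak(x, pk[1, ], baseline = "none")
  expect_equal(area, 1, tolerance = 5e-3)

  # half-window of a symmetric peak holds half the area
  half <- integrate_peak(x, list(left = pk$left_time[1], right = 50),
                         baseline = "none")
  expect_equal(half, 0.5, tolerance = 1e-2)

  # a linear baseline exactly under a ramp integrates to zero
  ramp <- chromatogram(seq(0, 10, 0.1), seq(2, 7, length.out = 101))
  expect_equal(integrate_peak(ramp, list(left = 1, right = 9),
                              baseline = "linear"), 0)

  expect_error(integrate_peak(x, list(left = 0, right = 50)), "domain")
})

test_that("peaks are assigned by retention time with co-elution groups", {
  lib <- default_rt_library()
  x <- gaussian_chromatogram(c(2, 3, 1), c(33, 48, 52))  # 3-Xylp, 3-Galp, 4-Glcp
  pk <- integrate_peaks(x, detect_peaks(x))
  asg <- assign_peaks(pk, lib)
  expect_equal(asg$label[order(asg$apex_time)],
               c("3-Xylp", "3-Galp", "4-Glcp"))
  expect_true(all(is.na(asg$shared_group)))

  # a peak away from every library time stays unassigned
  x2 <- gaussian_chromatogram(1, 90)
  asg2 <- assign_peaks(detect_peaks(x2), lib)
  expect_true(is.na(asg2$label))

  # a peak in the 2-/4-Xylp window fans out into a shared group
  x3 <- gaussian_chromatogram(1, 31)
  asg3 <- assign_peaks(detect_peaks(x3), lib)
  expect_setequal(asg3$label, c("2-Xylp", "4-Xylp"))
  expect_equal(unique(asg3$shared_group), "2-Xylp+4-Xylp")

  # two peaks inside one tolerance window is ambiguous
  x4 <- gaussian_chromatogram(c(1, 1), c(47.95, 48.05), sigma = 0.015)
  expect_error(assign_peaks(detect_peaks(x4, smooth = 1), lib), "ambiguous")

  # assignment neither creates nor destroys area
  expect_equal(sum(asg$area), sum(pk$area))
})

test_that("retention-time library validates tolerances and co-elution groups", {
  expect_error(rt_library(data.frame(label = "3-Galp", rt = 10,
                                     tolerance = 0)), "positive")
  expect_error(rt_library(data.frame(label = c("3-Galp", "4-Galp"),
                                     rt = c(10, 10), tolerance = 0.1,
                                     group = "bad")), "not a symmetric pair")
  lib <- rt_library(data.frame(label = c("2-Xylp", "4-Xylp"),
                               rt = c(10, 10), tolerance = 0.1,
                               group = "x"))
  expect_s3_class(lib, "rt_library")
})

test_that("simulator round-trip recovers true areas within 1% (noiseless)", {
  areas <- c(3, 1.5, 0.8)
  x <- gaussian_chromatogram(areas, c(40, 50, 60))
  pk <- integrate_peaks(x, detect_peaks(x), baseline = "none")
  expect_equal(pk$area, areas, tolerance = 1e-2)
})
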