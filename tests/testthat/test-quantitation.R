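# Detector response laws, shared-peak splitting, response-factor
# determination and FID/TIC comparison.

test_that("FID composition divides areas by response factors", {
  lib <- response_factor_library(c("3-Galp" = 1, "4-Galp" = 1,
                                   "4-Glcp" = 0.5, "3-Xylp" = 1))
  pk <- data.frame(label = c("3-Galp", "4-Galp"), area = c(5, 5))
  ct <- fid_composition(pk, lib)
  expect_equal(comp_vector(ct), c("3-Galp" = 50, "4-Galp" = 50))

  # agarose standard: areas in the 0.49 : 0.74 ratio are equimolar
  std <- data.frame(label = c("4-AnGalp", "3-Galp"), area = c(0.49, 0.74))
  ct <- fid_composition(std, default_response_factors())
  expect_equal(unname(comp_vector(ct)[c("4-AnGalp", "3-Galp")]), c(50, 50))

  # three peaks, areas (2,1,1), factors (1,0.5,1): moles 2:2:1 -> 40/40/20
  pk3 <- data.frame(label = c("3-Galp", "4-Glcp", "3-Xylp"),
                    area = c(2, 1, 1))
  ct3 <- fid_composition(pk3, lib)
  expect_equal(comp_vector(ct3)[c("3-Galp", "4-Glcp", "3-Xylp")],
               c("3-Galp" = 40, "4-Glcp" = 40, "3-Xylp" = 20))

  # missing factor is an error, never a silent 1.0
  expect_error(fid_composition(data.frame(label = "2-Manp", area = 1), lib),
               "2-Manp")
})

test_that("TIC composition divides areas by nominal mass", {
  # equal areas at equal masses (two mono-linked hexoses) are uniform
  pk <- data.frame(label = c("3-Galp", "4-Galp"), area = c(100, 100))
  ct <- tic_composition(pk)
  expect_equal(unname(comp_vector(ct)), c(50, 50), tolerance = 1e-12)

  # areas proportional to masses (351, 279) are equimolar
  pk2 <- data.frame(label = c("4-Glcp", "t-Xylp"), area = c(351, 279))
  expect_equal(unname(comp_vector(tic_composition(pk2))), c(50, 50))

  # masses 351 / 279 with areas 351 / 558 -> 33.33 / 66.67
  pk3 <- data.frame(label = c("4-Glcp", "t-Xylp"), area = c(351, 558))
  expect_equal(unname(comp_vector(tic_composition(pk3))[c("4-Glcp", "t-Xylp")]),
               c(100 / 3, 200 / 3), tolerance = 1e-9)

  # anhydro masses use the non-deuterated reductive-hydrolysis route
  pk4 <- data.frame(label = "4-AnGalp", area = 304)
  expect_equal(comp_vector(tic_composition(pk4)), c("4-AnGalp" = 100))
})

test_that("composition tables normalize to 100 and flag minors", {
  ct <- composition_table(c("3-Galp" = 7, "4-Glcp" = 3))
  expect_equal(sum(ct$mol_percent), 100, tolerance = 1e-6)
  ct2 <- composition_table(c("3-Galp" = 99.8, "4-Glcp" = 0.2))
  expect_true(ct2$minor[ct2$label == "4-Glcp"])
  expect_false(ct2$minor[ct2$label == "3-Galp"])
  expect_equal(nrow(ct2), 2L)  # minors flagged, never dropped
  expect_error(composition_table(c(a = -1, b = 2)), "negative")
})

test_that("shared peaks split proportionally to EIC areas and conserve area", {
  s <- split_shared_peak(100, c("2-Xylp" = 1, "4-Xylp" = 1))
  expect_equal(unname(s), c(50, 50))

  s <- split_shared_peak(100, c("2-Xylp" = 3, "4-Xylp" = 1))
  expect_equal(unname(s), c(75, 25))

  # degenerate ratio: everything to the detected member
  s <- split_shared_peak(42, c("2-Xylp" = 0, "4-Xylp" = 5))
  expect_equal(unname(s), c(0, 42))

  # exact conservation across random splits
  set.seed(42)
  for (i in 1:25) {
    area <- runif(1, 0, 1000)
    eic <- runif(2)
    s <- split_shared_peak(area, setNames(eic, c("a-Galp", "b-Galp")))
    expect_identical(sum(s), area)
  }

  expect_error(split_shared_peak(1, c(a = 0, b = 0)), "indeterminate")
  expect_error(split_shared_peak(1, c(a = 1, b = 1, c = 1)), "two members")
})

test_that("response factors are recovered from known-ratio standards", {
  # identity case
  expect_equal(determine_rf_from_standard(c(x = 1, ref = 1), "ref", 0.74),
               0.74)
  # the agarose determination: area ratio 0.6622 at 1:1 molar, ref 0.74
  expect_equal(determine_rf_from_standard(c("4-AnGalp" = 0.6622,
                                            "3-Galp" = 1),
                                          "3-Galp", 0.74),
               0.49, tolerance = 1e-3)
  # non-equimolar standard
  expect_equal(determine_rf_from_standard(c(x = 1, ref = 1), "ref", 0.8,
                                          molar_ratio = 2), 0.4)
  expect_error(determine_rf_from_standard(c(x = 1, ref = 0), "ref", 0.7),
               "zero reference")
})

test_that("rf determination inverts the simulator's response law", {
  # noiseless: exact recovery of the library factor
  spec <- simulation_spec(c("4-AnGalp" = 0.5, "3-Galp" = 0.5), seed = 1)
  x <- simulate_chromatogram(spec)
  pk <- integrate_peaks(x, detect_peaks(x), baseline = "none")
  asg <- assign_peaks(pk, default_rt_library())
  areas <- setNames(asg$area, asg$label)
  rf <- determine_rf_from_standard(areas[c("4-AnGalp", "3-Galp")],
                                   "3-Galp", 0.74)
  expect_equal(rf, 0.49, tolerance = 1e-6)

  # noisy: mean over 100 seeds within 1%
  nsd <- 0.01 * max(x$intensities)
  rfs <- vapply(1:100, function(s) {
    sp <- simulation_spec(c("4-AnGalp" = 0.5, "3-Galp" = 0.5), seed = s,
                          noise_sd = nsd)
    xs <- simulate_chromatogram(sp)
    pks <- integrate_peaks(xs, detect_peaks(xs, halfwidth = 0.5),
                           baseline = "none")
    a <- assign_peaks(pks, default_rt_library())
    v <- setNames(a$area, a$label)
    determine_rf_from_standard(v[c("4-AnGalp", "3-Galp")], "3-Galp", 0.74)
  }, numeric(1))
  expect_equal(mean(rfs), 0.49, tolerance = 0.01)
})

test_that("FID/TIC comparison flags over-represented labels", {
  fid <- composition_table(c("4-AnGalp" = 30, "3-Galp" = 70),
                           detector = "FID")
  tic <- composition_table(c("4-AnGalp" = 30, "3-Galp" = 70),
                           detector = "TIC")
  cmp <- compare_detectors(fid, tic)
  expect_equal(cmp$ratio, c(1, 1))
  expect_false(any(cmp$flagged))

  tic2 <- composition_table(c("4-AnGalp" = 15, "3-Galp" = 85),
                            detector = "TIC")
  cmp2 <- compare_detectors(fid, tic2)
  expect_true(cmp2$flagged[cmp2$label == "4-AnGalp"])

  # label present in only one table: omitted with a warning
  tic3 <- composition_table(c("4-AnGalp" = 30, "3-Galp" = 60,
                              "4-Glcp" = 10), detector = "TIC")
  expect_warning(cmp3 <- compare_detectors(fid, tic3), "4-Glcp")
  expect_false("4-Glcp" %in% cmp3$label)

  only <- composition_table(c("2-Manp" = 100))
  expect_error(compare_detectors(fid, only), "no labels")
})

test_that("replicate summaries report mean, sd and n per label", {
  r1 <- composition_table(c("3-Galp" = 60, "4-Glcp" = 40), sample_id = "a1")
  r2 <- composition_table(c("3-Galp" = 62, "4-Glcp" = 38), sample_id = "a2")
  s <- replicate_summary(list(r1, r2))
  expect_equal(s$mean_percent[s$label == "3-Galp"], 61)
  expect_equal(s$sd_percent[s$label == "3-Galp"], sd(c(60, 62)))
  expect_equal(unique(s$n), 2L)
})
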