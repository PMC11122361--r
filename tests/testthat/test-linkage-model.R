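# Linkage parsing, PMAA derivatization, symmetry, fragments and response
# factors.

test_that("linkage codes parse, canonicalize and round-trip", {
  lk <- parse_linkage("4-Glc*p*")
  expect_equal(lk$sugar, "Glc")
  expect_equal(lk$ring, "p")
  expect_equal(lk$linked_positions, 4L)
  expect_equal(format(lk), "4-Glcp")

  tx <- parse_linkage("t-Xylp")
  expect_length(tx$linked_positions, 0L)

  an <- parse_linkage("2,4-AnGalp")
  expect_equal(an$linked_positions, c(2L, 4L))
  expect_equal(an$anhydro_bridge, c(3L, 6L))

  # ring defaults: arabinose furanose, everything else pyranose
  expect_equal(parse_linkage("t-Ara")$ring, "f")
  expect_equal(parse_linkage("3-Gal")$ring, "p")

  # canonical labels round-trip for the whole shipped library
  for (lab in rt_labels())
    expect_equal(format(parse_linkage(lab)), lab)
})

test_that("malformed linkage codes fail with informative errors", {
  expect_error(parse_linkage("4-Hexp"), "unknown sugar|cannot parse")
  expect_error(parse_linkage("7-Galp"), "cannot parse|out of range")
  expect_error(parse_linkage("6-Xylp"), "out of range")
  expect_error(parse_linkage("3-AnGalp"), "collides")
  expect_error(parse_linkage("2-AnXylp"), "hexose")
  expect_error(parse_linkage("5-Galp"), "ring-closure")
})

test_that("derivatization produces the documented substitution patterns and masses", {
  d <- derivatize("4-Glcp", deuterate = TRUE)
  expect_equal(d$acetyl_positions, c(1L, 4L, 5L))
  expect_equal(d$methyl_positions, c(2L, 3L, 6L))
  expect_equal(d$nominal_mass, 351)
  expect_equal(d$nominal_mass,
               oracle_pmaa_mass(6, acetyl = c(1, 4, 5), methyl = c(2, 3, 6),
                                deuterated = TRUE))

  d <- derivatize("t-Xylp", deuterate = TRUE)
  expect_equal(d$acetyl_positions, c(1L, 5L))
  expect_equal(d$methyl_positions, c(2L, 3L, 4L))
  expect_equal(d$nominal_mass, 279)
  expect_equal(d$nominal_mass,
               oracle_pmaa_mass(5, acetyl = c(1, 5), methyl = c(2, 3, 4),
                                deuterated = TRUE))

  d <- derivatize("4-AnGalp")
  expect_equal(d$acetyl_positions, c(1L, 4L, 5L))
  expect_equal(d$methyl_positions, 2L)
  expect_equal(d$anhydro_positions, c(3L, 6L))
  expect_equal(d$nominal_mass, 304)
  expect_equal(d$nominal_mass,
               oracle_pmaa_mass(6, acetyl = c(1, 4, 5), methyl = 2,
                                anhydro = c(3, 6)))

  expect_error(derivatize("4-AnGalp", deuterate = TRUE), "anhydro")
})

test_that("every oxygen-bearing carbon is covered exactly once and masses match the group oracle", {
  for (lab in rt_labels()) {
    link <- parse_linkage(lab)
    deut <- is.null(link$anhydro_bridge)
    d <- derivatize(lab, deuterate = deut)
    cover <- sort(c(d$acetyl_positions, d$methyl_positions,
                    d$anhydro_positions))
    expect_equal(cover, sort(unique(cover)), info = lab)  # no overlap
    expect_true(1L %in% d$acetyl_positions, info = lab)
    n <- if (link$sugar %in% c("Xyl", "Ara")) 5L else 6L
    expect_equal(d$nominal_mass,
                 oracle_pmaa_mass(n, d$acetyl_positions, d$methyl_positions,
                                  d$anhydro_positions, deuterated = deut),
                 info = lab)
  }
})

test_that("each linked position adds 28 Da over the terminal variant", {
  cases <- list(c("4-Glcp", "t-Glcp"), c("2,3-Galp", "t-Galp"),
                c("2,4,6-Galp", "t-Galp"), c("3-Xylp", "t-Xylp"),
                c("2,4-Xylp", "t-Xylp"))
  for (cs in cases) {
    n_linked <- length(parse_linkage(cs[1])$linked_positions)
    expect_equal(pmaa_mass(cs[1]) - pmaa_mass(cs[2]), 28 * n_linked,
                 info = cs[1])
  }
})

test_that("symmetric pairs are detected by chain reversal and only there", {
  expect_true(is_symmetric_pair("2-Xylp", "4-Xylp"))
  expect_true(is_symmetric_pair("2,3,6-Galp", "2,4,6-Galp"))
  expect_false(is_symmetric_pair("3-Galp", "4-Galp"))
  expect_false(is_symmetric_pair("2-Xylp", "2-Manp"))      # sugar mismatch
  expect_false(is_symmetric_pair("4-AnGalp", "4-Galp"))    # anhydro excluded

  labs <- rt_labels()
  # involution and uniqueness of partners across the shipped library
  partners <- list()
  for (i in seq_along(labs)) for (j in seq_along(labs)) {
    if (i == j) next
    s <- is_symmetric_pair(labs[i], labs[j])
    expect_identical(s, is_symmetric_pair(labs[j], labs[i]))
    if (s) partners[[labs[i]]] <- c(partners[[labs[i]]], labs[j])
  }
  expect_true(all(lengths(partners) == 1L))
  # exactly the two known pairs
  got <- sort(vapply(names(partners), function(a)
    paste(sort(c(a, partners[[a]])), collapse = "/"), character(1)))
  expect_equal(unique(got),
               c("2,3,6-Galp/2,4,6-Galp", "2-Xylp/4-Xylp"))
})

test_that("fragment prediction follows single-cleavage arithmetic", {
  fr <- predict_fragments(derivatize("t-Xylp", deuterate = TRUE))
  expect_equal(nrow(fr), 8L)  # 4 C-C bonds x 2 retained sides

  # complementary fragments of one cleavage sum to a cleavage-independent
  # parent-related constant
  for (lab in c("t-Xylp", "4-Xylp", "4-Glcp", "2,3-Galp")) {
    fr <- predict_fragments(derivatize(lab, deuterate = TRUE))
    sums <- tapply(fr$mz, fr$cleavage, sum)
    expect_equal(length(unique(sums)), 1L, info = lab)
  }

  # the deuterium shift: +1 on every C-1 fragment, nothing else changes
  for (lab in c("4-Xylp", "3-Galp", "2,4,6-Galp")) {
    f1 <- predict_fragments(derivatize(lab, deuterate = TRUE))
    f0 <- predict_fragments(derivatize(lab, deuterate = FALSE))
    expect_equal(f1$mz[f1$side == "C1"] - f0$mz[f0$side == "C1"],
                 rep(1L, sum(f1$side == "C1")), info = lab)
    expect_equal(sort(f1$mz[f1$side == "Cn"]), sort(f0$mz[f0$side == "Cn"]),
                 info = lab)
  }

  # hand-computed fragment set of the deuterated 4-Xylp PMAA
  f4 <- predict_fragments(derivatize("4-Xylp", deuterate = TRUE))
  expect_setequal(f4$mz[f4$side == "C1"], c(74, 118, 162, 234))
  expect_setequal(f4$mz[f4$side == "Cn"], c(73, 145, 189, 233))

  # mirror pair: same molecule, but the label swaps sides, so the mass
  # multisets differ
  f2 <- predict_fragments(derivatize("2-Xylp", deuterate = TRUE))
  expect_false(setequal(f2$mz, f4$mz))

  expect_error(predict_fragments(derivatize("4-AnGalp")), "unsupported")
})

test_that("diagnostic ions are unique, label-bearing and maximally separated", {
  ions <- diagnostic_ions("2-Xylp", "4-Xylp")
  expect_named(ions, c("2-Xylp", "4-Xylp"))
  f2 <- predict_fragments(derivatize("2-Xylp", deuterate = TRUE))
  f4 <- predict_fragments(derivatize("4-Xylp", deuterate = TRUE))
  expect_true(ions[["2-Xylp"]] %in% setdiff(f2$mz[f2$side == "C1"], f4$mz))
  expect_true(ions[["4-Xylp"]] %in% setdiff(f4$mz[f4$side == "C1"], f2$mz))
  # maximal separation among unique label-bearing candidates
  seps <- abs(outer(setdiff(f2$mz[f2$side == "C1"], f4$mz),
                    setdiff(f4$mz[f4$side == "C1"], f2$mz), "-"))
  expect_equal(abs(ions[[1]] - ions[[2]]), max(seps))
  expect_error(diagnostic_ions("3-Galp", "4-Galp"), "not a symmetric pair")
})

test_that("response factors resolve from the library or the O-2 increment rule", {
  lib <- default_response_factors()
  expect_equal(response_factor("3-Galp", lib), 0.74)
  expect_equal(response_factor("4-AnGalp", lib), 0.49)
  expect_equal(response_factor("2,4-AnGalp", lib), 0.54)

  # increment rule alone reconstructs the 2,4-AnGalp factor
  base_only <- response_factor_library(
    c("4-AnGalp" = 0.49),
    increment_rules = list(list(position = 2L, delta = 0.05)))
  expect_equal(response_factor("2,4-AnGalp", base_only), 0.54)

  # no entry and no applicable rule fails loudly, naming the label
  expect_error(response_factor("2-Manp", base_only), "2-Manp")
  expect_error(response_factor_library(c("x-bad" = 1)), "cannot parse")
  expect_error(response_factor_library(c("3-Galp" = 0)), "\\(0, 2\\]")

  # symmetric-pair members respond identically (same molecule)
  expect_equal(response_factor("2-Xylp", lib), response_factor("4-Xylp", lib))
  expect_equal(response_factor("2,3,6-Galp", lib),
               response_factor("2,4,6-Galp", lib))
})
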