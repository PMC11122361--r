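# Independent oracles used across the suite. These deliberately take a
# different route than the package implementation: masses are obtained by
# assembling chemical group strings per backbone carbon and counting atoms
# with a tiny formula parser, not by increment arithmetic.

count_atoms <- function(group) {
  # parse strings like "CH2", "CHD", "OC2H3O2" into atom counts
  out <- c(C = 0L, H = 0L, D = 0L, O = 0L)
  for (m in regmatches(group, gregexpr("[CHDO][0-9]*", group))[[1L]]) {
    el <- substr(m, 1L, 1L)
    n <- if (nchar(m) > 1L) as.integer(substr(m, 2L, nchar(m))) else 1L
    out[el] <- out[el] + n
  }
  out
}

# group-contribution mass oracle for a PMAA alditol derivative
oracle_pmaa_mass <- function(n_backbone, acetyl, methyl, anhydro = integer(0),
                             deuterated = FALSE, deoxy = integer(0)) {
  groups <- character(0)
  for (i in seq_len(n_backbone)) {
    terminal <- i %in% c(1L, n_backbone)
    core <- if (terminal) "CH2" else "CH"
    if (i == 1L && deuterated) core <- "CHD"
    groups <- c(groups, core)
    if (i %in% acetyl) groups <- c(groups, "C2H3O2")    # O-C(=O)-CH3
    else if (i %in% methyl) groups <- c(groups, "OCH3") # O-methyl
    else if (i %in% deoxy) groups <- c(groups, "H")
  }
  if (length(anhydro)) groups <- c(groups, "O")  # shared ether bridge
  atoms <- Reduce(`+`, lapply(groups, count_atoms))
  sum(atoms * c(C = 12L, H = 1L, D = 2L, O = 16L)[names(atoms)])
}

# analytic Gaussian-peak chromatogram for integration oracles
gaussian_chromatogram <- function(areas, centers, sigma = 0.08,
                                  t = seq(20, 120, by = 0.02),
                                  detector = "FID", noise_sd = 0,
                                  sample_id = "fixture") {
  y <- numeric(length(t))
  for (i in seq_along(areas))
    y <- y + areas[i] * dnorm(t, centers[i], sigma)
  if (noise_sd > 0) y <- y + rnorm(length(t), 0, noise_sd)
  chromatogram(t, y, detector = detector, sample_id = sample_id)
}

comp_vector <- function(ct) setNames(ct$mol_percent, ct$label)

# labels shipped in the default retention-time library
rt_labels <- function() default_rt_library()$entries$label
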