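# Synthetic FID/TIC/EIC chromatogram generator: Gaussian peaks whose areas
# follow the detector response laws, plus baseline drift and Gaussian
# noise, so every pipeline stage has a ground-truth oracle.

#' Specify a synthetic chromatogram simulation
#'
#' Collects the composition, libraries, peak shape, detector law and noise
#' model for [simulate_chromatogram()]. Peak areas follow the
#' detector-specific response laws: on the FID basis, area = moles x
#' relative response factor; on the TIC basis, area = moles x nominal mass,
#' additionally multiplied by `anhydro_tic_suppression` for anhydro-sugar
#' PMAAs. The suppression factor emulates the reduced electron-impact
#' ionization efficiency observed for 3,6-anhydro-galactose derivatives;
#' its default of 0.5 is an illustrative choice (the true magnitude is not
#' quantified), and 1.0 switches the effect off.
#'
#' @param composition named numeric vector of mol fractions (normalized
#'   internally; percentages are accepted).
#' @param detector `"FID"` or `"TIC"`.
#' @param rt_lib retention-time library ([rt_library()]).
#' @param rf_lib response-factor library ([response_factor_library()]).
#' @param sigma Gaussian peak standard deviation, minutes.
#' @param total_moles total molar scale (arbitrary units).
#' @param anhydro_tic_suppression factor in (0, 1] applied to TIC areas of
#'   anhydro PMAAs.
#' @param noise_sd additive i.i.d. Gaussian noise standard deviation
#'   (intensity units).
#' @param baseline_slope linear baseline drift, intensity units per minute.
#' @param seed integer fixing the full output bitwise, or `NULL` to draw
#'   from the caller's RNG stream.
#' @param t_range,dt time grid (minutes).
#' @param sample_id sample tag.
#' @return object of class `simulation_spec`.
#' @export
simulation_spec <- function(composition, detector = c("FID", "TIC"),
                            rt_lib = default_rt_library(),
                            rf_lib = default_response_factors(),
                            sigma = 0.08, total_moles = 100,
                            anhydro_tic_suppression = 0.5,
                            noise_sd = 0, baseline_slope = 0, seed = 1L,
                            t_range = c(25, 110), dt = 0.02,
                            sample_id = "synthetic") {
  detector <- match.arg(detector)
  stopifnot(is.numeric(composition), !is.null(names(composition)),
            all(composition >= 0), sum(composition) > 0,
            sigma > 0, anhydro_tic_suppression > 0,
            anhydro_tic_suppression <= 1)
  names(composition) <- vapply(names(composition),
                               function(l) parse_linkage(l)$label,
                               character(1))
  missing <- setdiff(names(composition), rt_lib$entries$label)
  if (length(missing))
    stop("no retention time for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  structure(list(composition = composition / sum(composition),
                 detector = detector, rt_lib = rt_lib, rf_lib = rf_lib,
                 sigma = sigma, total_moles = total_moles,
                 anhydro_tic_suppression = anhydro_tic_suppression,
                 noise_sd = noise_sd, baseline_slope = baseline_slope,
                 seed = seed, t_range = t_range, dt = dt,
                 sample_id = sample_id),
            class = "simulation_spec")
}

.true_area <- function(spec, label, detector = spec$detector) {
  moles <- spec$total_moles * spec$composition[[label]]
  link <- parse_linkage(label)
  if (detector == "FID") {
    moles * response_factor(label, spec$rf_lib)
  } else {
    supp <- if (has_anhydro(link)) spec$anhydro_tic_suppression else 1
    moles * pmaa_mass(label) * supp
  }
}

.render_trace <- function(spec, areas, rts, detector, eic_mz = NULL,
                          sample_id = spec$sample_id) {
  t <- seq(spec$t_range[1L], spec$t_range[2L], by = spec$dt)
  y <- numeric(length(t))
  for (i in seq_along(areas))
    y <- y + areas[i] * stats::dnorm(t, mean = rts[i], sd = spec$sigma)
  y <- y + spec$baseline_slope * (t - t[1L])
  if (spec$noise_sd > 0) y <- y + stats::rnorm(length(t), 0, spec$noise_sd)
  chromatogram(t, y, detector = detector, eic_mz = eic_mz,
               sample_id = sample_id)
}

#' Simulate a chromatogram from a linkage composition
#'
#' One Gaussian peak per linkage at its library retention time, with area
#' set by the detector response law of the [simulation_spec()], plus linear
#' baseline drift and additive Gaussian noise. Deterministic (bitwise)
#' under the spec's seed.
#'
#' @param spec a `simulation_spec`.
#' @return a [chromatogram()].
#' @export
simulate_chromatogram <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  labels <- names(spec$composition)
  areas <- vapply(labels, function(l) .true_area(spec, l), numeric(1))
  rts <- spec$rt_lib$entries$rt[match(labels, spec$rt_lib$entries$label)]
  with_seed(spec$seed, .render_trace(spec, areas, rts, spec$detector))
}

#' Simulate one full sample: FID + TIC traces and diagnostic EICs
#'
#' Renders the FID and TIC chromatograms of a composition and, for every
#' co-elution group of the retention-time library with at least one member
#' present, the diagnostic extracted-ion chromatograms of both members
#' (EIC area proportional to the member's molar amount; an absent member
#' yields an empty trace). These EICs are what the quantitation stage uses
#' to split the shared peak.
#'
#' @param spec a `simulation_spec` (its `detector` field is ignored; both
#'   detectors are rendered).
#' @return list with elements `fid`, `tic` (chromatograms), `eics` (list of
#'   EIC chromatograms named `<label>@<mz>`), `truth` (the input mol
#'   fractions) and `sample_id`.
#' @export
simulate_sample <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  with_seed(spec$seed, {
    labels <- names(spec$composition)
    ent <- spec$rt_lib$entries
    rts <- ent$rt[match(labels, ent$label)]
    fid_areas <- vapply(labels, function(l) .true_area(spec, l, "FID"),
                        numeric(1))
    tic_areas <- vapply(labels, function(l) .true_area(spec, l, "TIC"),
                        numeric(1))
    fid <- .render_trace(spec, fid_areas, rts, "FID")
    tic <- .render_trace(spec, tic_areas, rts, "TIC")
    eics <- list()
    groups <- unique(stats::na.omit(ent$group))
    for (g in groups) {
      members <- ent$label[!is.na(ent$group) & ent$group == g]
      if (!any(members %in% labels)) next
      ions <- diagnostic_ions(members[1L], members[2L])
      rt_g <- ent$rt[match(members[1L], ent$label)]
      for (lab in members) {
        moles <- if (lab %in% labels)
          spec$total_moles * spec$composition[[lab]] else 0
        eic <- .render_trace(spec, moles, rt_g, "EIC",
                             eic_mz = ions[[lab]])
        eics[[paste0(lab, "@", ions[[lab]])]] <- eic
      }
    }
    list(fid = fid, tic = tic, eics = eics,
         truth = spec$composition, sample_id = spec$sample_id)
  })
}

#' Simulate a co-eluting symmetric pair with its diagnostic EICs
#'
#' Renders the composite (shared) peak of a symmetric PMAA pair at one
#' retention time plus the two diagnostic extracted-ion chromatograms whose
#' areas are proportional to the molar ratio, for exercising
#' [split_shared_peak()] end to end.
#'
#' @param pair character vector of the two member labels (must satisfy
#'   [is_symmetric_pair()]).
#' @param molar_ratio numeric vector of length 2, the members' molar
#'   amounts (e.g. `c(3, 1)`).
#' @param spec a `simulation_spec` providing libraries, peak shape, grid
#'   and noise (its composition is ignored).
#' @param shared_rt retention time of the shared peak; defaults to the
#'   library time of the first member.
#' @return list with `composite` (chromatogram on the spec's detector) and
#'   `eics` (list of two EIC chromatograms named by member label).
#' @export
simulate_pair_eics <- function(pair, molar_ratio, spec, shared_rt = NULL) {
  stopifnot(length(pair) == 2L, length(molar_ratio) == 2L,
            all(molar_ratio >= 0), sum(molar_ratio) > 0)
  if (!is_symmetric_pair(pair[1L], pair[2L]))
    stop("'", pair[1L], "' and '", pair[2L], "' are not a symmetric pair",
         call. = FALSE)
  pair <- vapply(pair, function(l) parse_linkage(l)$label, character(1))
  ent <- spec$rt_lib$entries
  shared_rt <- shared_rt %||% ent$rt[match(pair[1L], ent$label)]
  per_mole <- vapply(pair, function(l) {
    if (spec$detector == "FID") response_factor(l, spec$rf_lib)
    else pmaa_mass(l)
  }, numeric(1))
  ions <- diagnostic_ions(pair[1L], pair[2L])
  with_seed(spec$seed, {
    composite <- .render_trace(spec, sum(molar_ratio * per_mole), shared_rt,
                               spec$detector)
    eics <- stats::setNames(lapply(seq_len(2L), function(i)
      .render_trace(spec, molar_ratio[i], shared_rt, "EIC",
                    eic_mz = ions[[pair[i]]])), pair)
    list(composite = composite, eics = eics)
  })
}

#' Load the shipped synthetic species linkage profiles
#'
#' Six red-seaweed linkage compositions (percent, summing to 100 each) used
#' as the default study design of [simulate_dataset()]. Major values follow
#' published FID-based compositions for the six species; minor linkages are
#' plausible fill. The profiles are synthetic study conditions, not
#' measured data.
#'
#' @return named list of named numeric vectors.
#' @export
default_species_profiles <- function() {
  x <- jsonlite::read_json(system.file("extdata", "species_profiles.json",
                                       package = "pmaatools",
                                       mustWork = TRUE),
                           simplifyVector = TRUE)
  lapply(x$profiles, unlist)
}

# Dirichlet draw: composition perturbed at precision 1/within_noise.
.perturb_composition <- function(p, within_noise) {
  p <- p / sum(p)
  if (within_noise <= 0) return(p)
  alpha <- p / within_noise
  g <- stats::rgamma(length(p), shape = alpha, rate = 1)
  if (sum(g) == 0) return(p)
  stats::setNames(g / sum(g), names(p))
}

#' Simulate a multi-species, replicated chromatogram dataset
#'
#' For each species profile and replicate, draws a perturbed composition
#' from a Dirichlet distribution centered on the profile (concentration
#' `profile / within_noise`; `within_noise = 0` reproduces the profile
#' exactly) and renders the full sample (FID, TIC, diagnostic EICs) with
#' the stated noise model. Ground-truth compositions are returned alongside
#' the traces. The default `within_noise` of 0.002 yields replicate
#' scatter of roughly one to two percentage points on major linkages,
#' comparable to duplicate-experiment variation in practice.
#'
#' @param profiles named list of named composition vectors; defaults to
#'   the shipped six-species design.
#' @param replicates replicates per species (>= 1; the study design uses
#'   two separate experiments per sample).
#' @param within_noise Dirichlet perturbation scale (inverse precision).
#' @param seed integer seed fixing the whole dataset.
#' @param ... further arguments to [simulation_spec()] (noise_sd, sigma,
#'   anhydro_tic_suppression, ...).
#' @return object of class `linkage_dataset`: list with `samples` (each a
#'   [simulate_sample()] result plus `species` and `replicate`) and
#'   `truth` (long data.frame sample_id/species/replicate/label/percent).
#' @export
simulate_dataset <- function(profiles = default_species_profiles(),
                             replicates = 2L, within_noise = 0.002,
                             seed = 1L, ...) {
  stopifnot(length(profiles) >= 2L, replicates >= 1L)
  with_seed(seed, {
    samples <- list()
    truth <- list()
    for (sp in names(profiles)) {
      for (r in seq_len(replicates)) {
        comp <- .perturb_composition(profiles[[sp]], within_noise)
        id <- paste0(sp, "_rep", r)
        spec <- simulation_spec(comp, seed = NULL, sample_id = id, ...)
        s <- simulate_sample(spec)
        s$species <- sp
        s$replicate <- r
        samples[[id]] <- s
        truth[[id]] <- data.frame(sample_id = id, species = sp,
                                  replicate = r, label = names(comp),
                                  percent = 100 * as.numeric(comp),
                                  stringsAsFactors = FALSE)
      }
    }
    structure(list(samples = samples, truth = do.call(rbind, truth)),
              class = "linkage_dataset")
  })
}

#' @export
print.linkage_dataset <- function(x, ...) {
  cat("<linkage_dataset> ", length(x$samples), " samples (",
      length(unique(x$truth$species)), " species x ",
      max(x$truth$replicate), " replicates)\n", sep = "")
  invisible(x)
}

#' Write a simulated dataset to chromatogram and truth CSV files
#'
#' @param ds a `linkage_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "linkage_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in ds$samples) {
    base <- file.path(dir, s$sample_id)
    write_chromatogram(s$fid, paste0(base, "_FID.csv"))
    write_chromatogram(s$tic, paste0(base, "_TIC.csv"))
    for (nm in names(s$eics))
      write_chromatogram(s$eics[[nm]],
                         paste0(base, "_EIC_", gsub("[^A-Za-z0-9@,-]", "_",
                                                    nm), ".csv"))
  }
  utils::write.csv(ds$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}
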