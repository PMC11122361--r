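# Detector-specific conversion of assigned peak areas into relative molar
# linkage compositions, shared-peak splitting and response-factor
# determination from standards.

#' Construct a relative linkage composition table
#'
#' Normalizes per-label molar amounts to percentages summing to 100.
#' Internally everything stays at full precision; [format_composition()]
#' mirrors the integer-percent reporting convention of published linkage
#' tables. Labels below `minor_floor` percent are flagged `minor` but never
#' dropped.
#'
#' @param moles named numeric vector of (relative) molar amounts, >= 0 with
#'   a positive sum.
#' @param sample_id sample tag.
#' @param detector quantitation basis, `"FID"` or `"TIC"`.
#' @param provenance optional character vector parallel to `moles`
#'   (`"direct peak"` or `"split share"`).
#' @param minor_floor percent threshold for the `minor` flag.
#' @return object of class `composition_table`: a data.frame with columns
#'   `label`, `mol_percent`, `provenance`, `minor`, plus `sample_id` and
#'   `detector` attributes.
#' @export
composition_table <- function(moles, sample_id = "", detector = c("FID", "TIC"),
                              provenance = NULL, minor_floor = 0.5) {
  detector <- match.arg(detector)
  stopifnot(is.numeric(moles), !is.null(names(moles)))
  if (any(moles < 0)) stop("negative molar amount", call. = FALSE)
  if (sum(moles) <= 0) stop("composition has zero total", call. = FALSE)
  pct <- 100 * moles / sum(moles)
  out <- data.frame(label = names(moles),
                    mol_percent = as.numeric(pct),
                    provenance = provenance %||% rep("direct peak",
                                                     length(moles)),
                    minor = as.numeric(pct) < minor_floor,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mol_percent), ]
  rownames(out) <- NULL
  structure(out, class = c("composition_table", "data.frame"),
            sample_id = sample_id, detector = detector)
}

#' @export
print.composition_table <- function(x, ...) {
  cat("<composition_table> sample '", attr(x, "sample_id"), "' (",
      attr(x, "detector"), " basis), ", nrow(x), " linkages\n", sep = "")
  print.data.frame(format_composition(x), row.names = FALSE)
  invisible(x)
}

#' Round a composition table for reporting
#'
#' @param x a `composition_table`.
#' @param digits 0 (integer percent, the conventional presentation) or more
#'   decimals.
#' @return data.frame with rounded `mol_percent`.
#' @export
format_composition <- function(x, digits = 0) {
  out <- as.data.frame(x)
  out$mol_percent <- round(out$mol_percent, digits)
  out
}

composition_values <- function(x) {
  stats::setNames(x$mol_percent, x$label)
}

.check_resolved <- function(peaks) {
  if (is.null(peaks$shared_group)) return(invisible(NULL))
  shared <- !is.na(peaks$shared_group)
  prov <- peaks$provenance
  if (is.null(prov)) prov <- rep("", nrow(peaks))
  if (any(shared & prov != "split share"))
    stop("peak table still contains unsplit shared groups; run",
         " split_shared_peak() / quantify_sample() first", call. = FALSE)
}

#' FID-based relative molar composition from assigned peak areas
#'
#' Applies the response-factor law: moles are proportional to peak area
#' divided by the PMAA's relative molar FID response factor, so a smaller
#' factor inflates the molar share of an under-responding derivative (this
#' orientation is what recovers a 1:1 molar ratio from the smaller anhydro
#' peak of an equimolar agarose standard). A missing factor is an error;
#' there is no silent fallback to 1.0.
#'
#' @param peaks data.frame with `label` and `area` columns (shared peaks
#'   already split; rows with `NA` labels are dropped with a message).
#' @param lib a [response_factor_library()].
#' @param sample_id sample tag (defaults to the one on `peaks`, if any).
#' @param minor_floor see [composition_table()].
#' @return a `composition_table` on the FID basis.
#' @export
fid_composition <- function(peaks, lib, sample_id = "", minor_floor = 0.5) {
  peaks <- .drop_unassigned(peaks)
  .check_resolved(peaks)
  factors <- vapply(peaks$label, function(l) response_factor(l, lib),
                    numeric(1))
  moles <- peaks$area / factors
  .aggregate_composition(peaks, moles, sample_id, "FID", minor_floor)
}

#' TIC-based relative molar composition from assigned peak areas
#'
#' Applies the total-ion-current law used in whole-cell-wall protocols:
#' moles proportional to peak area divided by the PMAA's molecular mass.
#' Masses default to the route-appropriate nominal masses from the linkage
#' model (C-1 deuterated for non-anhydro linkages, non-deuterated for
#' anhydro linkages). No anhydro response correction is applied on the TIC
#' basis; the FID/TIC discrepancy for anhydro sugars is surfaced by
#' [compare_detectors()] instead.
#'
#' @param peaks data.frame with `label` and `area` columns (shared peaks
#'   already split).
#' @param masses optional named numeric vector of masses overriding the
#'   defaults.
#' @inheritParams fid_composition
#' @return a `composition_table` on the TIC basis.
#' @export
tic_composition <- function(peaks, masses = NULL, sample_id = "",
                            minor_floor = 0.5) {
  peaks <- .drop_unassigned(peaks)
  .check_resolved(peaks)
  m <- vapply(peaks$label, function(l) {
    if (!is.null(masses) && l %in% names(masses)) masses[[l]]
    else pmaa_mass(l)
  }, numeric(1))
  moles <- peaks$area / m
  .aggregate_composition(peaks, moles, sample_id, "TIC", minor_floor)
}

.drop_unassigned <- function(peaks) {
  if (is.null(peaks$label)) stop("peak table has no labels", call. = FALSE)
  drop <- is.na(peaks$label)
  if (any(drop))
    message(sum(drop), " unassigned peak(s) excluded from composition")
  peaks[!drop, , drop = FALSE]
}

.aggregate_composition <- function(peaks, moles, sample_id, detector,
                                   minor_floor) {
  agg <- tapply(moles, peaks$label, sum)
  prov <- tapply(peaks$provenance %||% rep("direct peak", nrow(peaks)),
                 peaks$label, function(p) paste(unique(p), collapse = "; "))
  composition_table(stats::setNames(as.numeric(agg), names(agg)),
                    sample_id = sample_id, detector = detector,
                    provenance = as.character(prov[names(agg)]),
                    minor_floor = minor_floor)
}

#' Split a shared symmetric-pair peak from extracted-ion areas
#'
#' Co-eluting symmetric PMAA pairs share one FID/TIC peak; the molar ratio
#' inside it is read from diagnostic extracted-ion chromatogram areas (one
#' label-bearing ion per member). Shares are proportional to the EIC areas
#' and sum exactly to the shared area.
#'
#' @param shared_area total area of the shared peak.
#' @param eic_areas named numeric vector of exactly two diagnostic EIC
#'   areas (>= 0, not both zero), named by member label.
#' @return named numeric vector of the two member areas.
#' @examples
#' split_shared_peak(100, c("2-Xylp" = 3, "4-Xylp" = 1))  # 75 / 25
#' @export
split_shared_peak <- function(shared_area, eic_areas) {
  if (length(eic_areas) != 2L)
    stop("shared-peak splitting supports exactly two members, got ",
         length(eic_areas), call. = FALSE)
  if (is.null(names(eic_areas)) || any(!nzchar(names(eic_areas))))
    stop("eic_areas must be named by member label", call. = FALSE)
  if (any(eic_areas < 0)) stop("negative EIC area", call. = FALSE)
  if (sum(eic_areas) == 0)
    stop("indeterminate split: both diagnostic EIC areas are zero",
         call. = FALSE)
  first <- shared_area * eic_areas[[1L]] / sum(eic_areas)
  out <- c(first, shared_area - first)  # exact conservation
  names(out) <- names(eic_areas)
  out
}

#' Determine a FID response factor from a known-ratio standard
#'
#' Given a standard containing two PMAAs at a known molar ratio (for
#' agarose, 4-AnGalp : 3-Galp = 1 : 1) and the response factor of the
#' reference member, the unknown factor follows from the area ratio:
#' `factor_x = ref_factor * (area_x / area_ref) / (mol_x / mol_ref)`.
#'
#' @param areas named numeric vector of two peak areas.
#' @param ref_label name of the reference member in `areas`.
#' @param ref_factor its response factor.
#' @param molar_ratio known molar ratio of the other member to the
#'   reference (default 1, i.e. equimolar).
#' @return the response factor of the non-reference member.
#' @examples
#' determine_rf_from_standard(c("4-AnGalp" = 0.49, "3-Galp" = 0.74),
#'                            ref_label = "3-Galp", ref_factor = 0.74)
#' @export
determine_rf_from_standard <- function(areas, ref_label, ref_factor,
                                       molar_ratio = 1) {
  if (length(areas) != 2L || is.null(names(areas)))
    stop("areas must be a named vector of two peak areas", call. = FALSE)
  if (!ref_label %in% names(areas))
    stop("ref_label '", ref_label, "' not found in areas", call. = FALSE)
  area_ref <- areas[[ref_label]]
  if (area_ref <= 0) stop("zero reference area", call. = FALSE)
  area_x <- areas[[setdiff(names(areas), ref_label)]]
  ref_factor * (area_x / area_ref) / molar_ratio
}

#' Compare FID- and TIC-based compositions of one sample
#'
#' Reports the per-label ratio of FID to TIC relative percentages and flags
#' labels whose FID share exceeds the TIC share by more than `threshold`
#' (default 20%). On real and simulated data the flagged labels are the
#' 3,6-anhydro-galactose PMAAs, which under-respond in electron-impact
#' ionization relative to FID.
#'
#' @param fid,tic `composition_table`s of the same sample.
#' @param threshold flag labels with `ratio > 1 + threshold`.
#' @return data.frame with `label`, `fid_percent`, `tic_percent`, `ratio`,
#'   `flagged`, restricted to the labels present in both tables (a warning
#'   lists omissions).
#' @export
compare_detectors <- function(fid, tic, threshold = 0.2) {
  f <- composition_values(fid); g <- composition_values(tic)
  common <- intersect(names(f), names(g))
  if (length(common) == 0L)
    stop("FID and TIC tables share no labels", call. = FALSE)
  only <- c(setdiff(names(f), names(g)), setdiff(names(g), names(f)))
  if (length(only))
    warning("label(s) present in only one table omitted from ratios: ",
            paste(only, collapse = ", "), call. = FALSE)
  out <- data.frame(label = common,
                    fid_percent = as.numeric(f[common]),
                    tic_percent = as.numeric(g[common]),
                    stringsAsFactors = FALSE)
  out$ratio <- out$fid_percent / out$tic_percent
  out$flagged <- out$ratio > 1 + threshold
  out[order(-out$ratio), ]
}

#' Mean and standard deviation of linkage compositions across replicates
#'
#' Separate experiments on the same sample are quantified independently;
#' this utility reports per-label mean, sample standard deviation and
#' replicate count, the conventional presentation of replicate linkage
#' tables. Labels absent from a replicate contribute 0%.
#'
#' @param comps list of `composition_table`s (the replicates).
#' @return data.frame with `label`, `mean_percent`, `sd_percent`, `n`.
#' @export
replicate_summary <- function(comps) {
  stopifnot(length(comps) >= 1L)
  labels <- sort(unique(unlist(lapply(comps, function(x) x$label))))
  mat <- vapply(comps, function(x) {
    v <- composition_values(x)
    out <- stats::setNames(numeric(length(labels)), labels)
    out[names(v)] <- v
    out
  }, numeric(length(labels)))
  mat <- matrix(mat, nrow = length(labels),
                dimnames = list(labels, NULL))
  data.frame(label = labels,
             mean_percent = rowMeans(mat),
             sd_percent = apply(mat, 1L, stats::sd),
             n = length(comps),
             row.names = NULL, stringsAsFactors = FALSE)
}
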