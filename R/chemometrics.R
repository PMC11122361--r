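# Chromatogram normalization to the 4-Glcp anchor, feature-matrix assembly
# and Z-score standardized PCA.

#' Normalize a chromatogram to the 4-Glcp anchor peak
#'
#' Truncates the trace to the analysis window and rescales both axes by the
#' anchor peak apex: every retention time is divided by the anchor apex
#' time (making the anchor land at relative time 1) and every intensity by
#' the anchor apex intensity (relative abundance 1). The 4-Glcp PMAA, from
#' cellulose, is present in every sample, which is what makes it a usable
#' internal anchor without any peak assignment of the rest of the trace.
#' Normalized traces of the same material acquired with a uniformly
#' stretched time axis coincide.
#'
#' @param x a `chromatogram`.
#' @param rt_lib an [rt_library()] carrying the anchor's nominal retention
#'   time.
#' @param anchor anchor linkage label (default `"4-Glcp"`).
#' @param window retention-time window (minutes) kept for analysis.
#' @param anchor_rel_tol relative tolerance for locating the anchor: peaks
#'   within `anchor_rel_tol * anchor_rt` of the library time are anchor
#'   candidates (generous by design, so drifted or stretched runs still
#'   normalize); among candidates the tallest is taken.
#' @param ... passed to [detect_peaks()].
#' @return object of class `normalized_trace`: list with `rel_time`
#'   (strictly increasing, anchor at 1), `rel_intensity` (anchor apex 1),
#'   `sample_id`, `detector`.
#' @export
normalize_trace <- function(x, rt_lib = default_rt_library(),
                            anchor = "4-Glcp", window = c(25, 110),
                            anchor_rel_tol = 0.12, ...) {
  stopifnot(inherits(x, "chromatogram"))
  anchor <- parse_linkage(anchor)$label
  ent <- rt_lib$entries
  if (!anchor %in% ent$label)
    stop("anchor '", anchor, "' not in retention-time library",
         call. = FALSE)
  anchor_rt <- ent$rt[match(anchor, ent$label)]
  keep <- x$times >= window[1L] & x$times <= window[2L]
  if (sum(keep) < 3L)
    stop("window [", window[1L], ", ", window[2L],
         "] leaves no usable trace", call. = FALSE)
  xt <- chromatogram(x$times[keep], x$intensities[keep],
                     detector = x$detector, eic_mz = x$eic_mz,
                     sample_id = x$sample_id)
  peaks <- detect_peaks(xt, ...)
  cand <- which(abs(peaks$apex_time - anchor_rt) <=
                  anchor_rel_tol * anchor_rt)
  if (length(cand) == 0L)
    stop("normalization failed: anchor peak '", anchor,
         "' not found near ", anchor_rt, " min", call. = FALSE)
  apex <- cand[which.max(peaks$height[cand])]
  t0 <- peaks$apex_time[apex]
  i0 <- peaks$height[apex]
  if (i0 <= 0) stop("anchor peak has non-positive height", call. = FALSE)
  structure(list(rel_time = xt$times / t0,
                 rel_intensity = xt$intensities / i0,
                 sample_id = x$sample_id, detector = x$detector),
            class = "normalized_trace")
}

#' Resample normalized traces onto a common relative-time grid
#'
#' Linear interpolation of each trace onto a uniform grid spanning the
#' intersection of the traces' relative-time ranges, making traces with
#' different acquisition rates commensurable for PCA. No smoothing is
#' applied; a grid value that coincides with an original sample point
#' reproduces it exactly.
#'
#' @param traces list of `normalized_trace` objects.
#' @param n_points grid size (default 2000).
#' @return numeric matrix, one row per trace (rownames are sample ids,
#'   column names the grid relative times).
#' @export
resample_to_grid <- function(traces, n_points = 2000L) {
  stopifnot(length(traces) >= 1L)
  lo <- max(vapply(traces, function(s) min(s$rel_time), numeric(1)))
  hi <- min(vapply(traces, function(s) max(s$rel_time), numeric(1)))
  if (lo >= hi) stop("traces have disjoint relative-time ranges",
                     call. = FALSE)
  grid <- seq(lo, hi, length.out = n_points)
  m <- t(vapply(traces, function(s)
    stats::approx(s$rel_time, s$rel_intensity, xout = grid)$y,
    numeric(n_points)))
  rownames(m) <- vapply(traces, function(s)
    if (nzchar(s$sample_id)) s$sample_id else NA_character_, character(1))
  colnames(m) <- signif(grid, 6)
  m
}

#' Z-score standardize the columns of a feature matrix
#'
#' Centers each column to mean zero and scales to unit standard deviation.
#' The population (n denominator) convention is used, fixed for
#' reproducibility. Zero-variance columns carry no information and are set
#' to all-zero with a warning rather than producing divisions by zero.
#'
#' @param m numeric matrix with at least two rows (samples x variables).
#' @return standardized matrix of the same shape.
#' @export
zscore <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2L)
    stop("Z-score standardization needs at least 2 rows", call. = FALSE)
  mu <- colMeans(m)
  sdp <- sqrt(colMeans(sweep(m, 2L, mu)^2))  # population convention
  zero <- sdp == 0
  if (any(zero)) {
    warning(sum(zero), " zero-variance column(s) set to zero",
            call. = FALSE)
    sdp[zero] <- 1
  }
  out <- sweep(sweep(m, 2L, mu), 2L, sdp, "/")
  out[, zero] <- 0
  out
}

#' Principal component analysis via singular value decomposition
#'
#' Column-centers the input (a no-op on standardized data) and decomposes
#' it. Loadings are orthonormal; scores are the centered data projected
#' onto them; explained-variance fractions are the squared singular values
#' over their total, hence non-increasing. The sign of each component is
#' fixed so its largest-magnitude loading is positive, making results
#' deterministic. Columns that are identically zero (dropped variables
#' after standardization) are removed first.
#'
#' @param m numeric matrix, samples x variables, at least 2 rows. Pass the
#'   output of [zscore()] or set `standardize = TRUE`.
#' @param n_components number of components to keep; defaults to
#'   `min(nrow - 1, ncol)` and may not exceed it.
#' @param standardize apply [zscore()] internally first.
#' @return object of class `pca_result`: list with `scores`
#'   (samples x components), `loadings` (variables x components,
#'   orthonormal), `explained_variance` (fractions, non-increasing),
#'   `n_components` and `variables` (column names kept).
#' @export
pca <- function(m, n_components = NULL, standardize = FALSE) {
  m <- as.matrix(m)
  if (nrow(m) < 2L) stop("PCA needs at least 2 rows", call. = FALSE)
  if (standardize) m <- zscore(m)
  nonzero <- colSums(m != 0) > 0L
  if (!any(nonzero)) stop("all columns are zero", call. = FALSE)
  m <- m[, nonzero, drop = FALSE]
  max_k <- min(nrow(m) - 1L, ncol(m))
  k <- n_components %||% max_k
  if (k > max_k)
    stop("n_components = ", k, " exceeds min(rows - 1, cols) = ", max_k,
         call. = FALSE)
  centered <- sweep(m, 2L, colMeans(m))
  sv <- svd(centered)
  total <- sum(sv$d^2)
  if (total == 0) total <- 1  # degenerate: identical rows, zero variance
  flip <- vapply(seq_len(k), function(j) {
    v <- sv$v[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  loadings <- sweep(sv$v[, seq_len(k), drop = FALSE], 2L, flip, "*")
  rownames(loadings) <- colnames(m)
  scores <- centered %*% loadings
  structure(list(scores = scores,
                 loadings = loadings,
                 explained_variance = sv$d[seq_len(k)]^2 / total,
                 n_components = k,
                 variables = colnames(m)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result> ", nrow(x$scores), " samples, ", x$n_components,
      " components\n  explained variance: ",
      paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Assemble a PCA feature matrix from composition tables
#'
#' One row per composition table, one column per linkage label seen in any
#' of them (absent labels contribute 0%).
#'
#' @param comps list of `composition_table`s.
#' @return numeric matrix (samples x labels), rownames from sample ids.
#' @export
composition_matrix <- function(comps) {
  labels <- sort(unique(unlist(lapply(comps, function(x) x$label))))
  m <- t(vapply(comps, function(x) {
    v <- composition_values(x)
    out <- stats::setNames(numeric(length(labels)), labels)
    out[names(v)] <- v
    out
  }, numeric(length(labels))))
  rownames(m) <- vapply(comps, function(x) attr(x, "sample_id"),
                        character(1))
  m
}
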