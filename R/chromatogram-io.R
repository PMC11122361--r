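# Chromatogram container, delimited-text I/O, peak detection/integration and
# retention-time based peak assignment.

#' Construct a chromatogram
#'
#' A time/intensity trace from one detector. Times are minutes throughout
#' the package; intensities are arbitrary detector units and are never
#' compared across detectors without quantitation.
#'
#' @param times numeric vector, strictly increasing, minutes.
#' @param intensities numeric vector of the same length (negatives are
#'   allowed: noisy baselines dip below zero).
#' @param detector one of `"FID"`, `"TIC"`, `"EIC"`.
#' @param eic_mz integer m/z; required iff `detector == "EIC"`.
#' @param sample_id character tag carried through the pipeline.
#' @return object of class `chromatogram`.
#' @export
chromatogram <- function(times, intensities, detector = c("FID", "TIC", "EIC"),
                         eic_mz = NULL, sample_id = "") {
  detector <- match.arg(detector)
  times <- as.numeric(times); intensities <- as.numeric(intensities)
  if (length(times) == 0L) stop("empty chromatogram", call. = FALSE)
  if (length(times) != length(intensities))
    stop("times and intensities differ in length", call. = FALSE)
  if (anyNA(times) || anyNA(intensities))
    stop("chromatogram contains missing values", call. = FALSE)
  d <- diff(times)
  if (any(d <= 0)) {
    row <- which(d <= 0)[1L] + 1L
    stop("times must be strictly increasing; violation at row ", row,
         call. = FALSE)
  }
  if (detector == "EIC") {
    if (is.null(eic_mz)) stop("EIC chromatogram requires eic_mz", call. = FALSE)
    eic_mz <- as.integer(eic_mz)
  } else {
    eic_mz <- NULL
  }
  structure(list(times = times, intensities = intensities,
                 detector = detector, eic_mz = eic_mz,
                 sample_id = sample_id),
            class = "chromatogram")
}

#' @export
print.chromatogram <- function(x, ...) {
  cat("<chromatogram> ", x$detector,
      if (!is.null(x$eic_mz)) paste0(" m/z ", x$eic_mz),
      if (nzchar(x$sample_id)) paste0(" [", x$sample_id, "]"),
      ": ", length(x$times), " points, ",
      sprintf("%.2f-%.2f min", min(x$times), max(x$times)), "\n", sep = "")
  invisible(x)
}

#' Read a chromatogram from delimited text
#'
#' Two-column time/intensity text (CSV or TSV), with an optional header row
#' (`time_min,intensity`) and optional leading comment lines of the form
#' `# key: value` carrying `detector`, `sample_id` and, for extracted-ion
#' traces, `mz`. The delimiter is taken from `delim` or guessed from the
#' first data line. Non-numeric cells and non-increasing times are rejected
#' with the offending row number.
#'
#' @param path file path.
#' @param delim field delimiter; `NULL` to auto-detect comma vs tab.
#' @param detector detector tag used when the file header does not carry
#'   one.
#' @param sample_id sample tag used when the header does not carry one.
#' @return a [chromatogram()].
#' @export
read_chromatogram <- function(path, delim = NULL, detector = "FID",
                              sample_id = "") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty chromatogram file: ", path,
                                call. = FALSE)
  meta <- list()
  is_meta <- grepl("^\\s*#", lines)
  for (l in lines[is_meta]) {
    m <- regmatches(l, regexec("^\\s*#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", l))[[1L]]
    if (length(m) == 3L) meta[[m[2L]]] <- trimws(m[3L])
  }
  body <- lines[!is_meta]
  if (length(body) == 0L) stop("no data rows in ", path, call. = FALSE)
  if (is.null(delim)) delim <- if (grepl("\t", body[1L])) "\t" else ","
  rows <- strsplit(body, delim, fixed = TRUE)
  first <- suppressWarnings(as.numeric(rows[[1L]]))
  has_header <- anyNA(first)
  if (has_header) rows <- rows[-1L]
  if (length(rows) == 0L) stop("no data rows in ", path, call. = FALSE)
  n_offset <- if (has_header) 1L else 0L
  parsed <- matrix(NA_real_, nrow = length(rows), ncol = 2L)
  for (i in seq_along(rows)) {
    cells <- rows[[i]]
    if (length(cells) < 2L)
      stop("row ", i + n_offset, " of ", path, " has fewer than 2 columns",
           call. = FALSE)
    vals <- suppressWarnings(as.numeric(cells[1:2]))
    if (anyNA(vals))
      stop("non-numeric cell at row ", i + n_offset, " of ", path,
           call. = FALSE)
    parsed[i, ] <- vals
  }
  d <- diff(parsed[, 1L])
  if (any(d <= 0)) {
    row <- which(d <= 0)[1L] + 1L + n_offset
    stop("times not strictly increasing at row ", row, " of ", path,
         call. = FALSE)
  }
  chromatogram(parsed[, 1L], parsed[, 2L],
               detector = meta$detector %||% detector,
               eic_mz = if (!is.null(meta$mz)) as.integer(meta$mz),
               sample_id = meta$sample_id %||% sample_id)
}

#' Write a chromatogram as delimited text
#'
#' Inverse of [read_chromatogram()]: metadata header comments, a column
#' header and full-precision values, so a write/read round trip reproduces
#' the in-memory trace exactly.
#'
#' @param x a `chromatogram`.
#' @param path output file path.
#' @param delim field delimiter.
#' @return `path`, invisibly.
#' @export
write_chromatogram <- function(x, path, delim = ",") {
  stopifnot(inherits(x, "chromatogram"))
  header <- c(paste0("# detector: ", x$detector),
              if (!is.null(x$eic_mz)) paste0("# mz: ", x$eic_mz),
              if (nzchar(x$sample_id)) paste0("# sample_id: ", x$sample_id),
              paste0("time_min", delim, "intensity"))
  body <- paste0(sprintf("%.17g", x$times), delim,
                 sprintf("%.17g", x$intensities))
  writeLines(c(header, body), path)
  invisible(path)
}

.moving_average <- function(y, width) {
  if (width <= 1L) return(y)
  if (width %% 2L == 0L) width <- width + 1L
  k <- rep(1 / width, width)
  pad <- (width - 1L) %/% 2L
  ypad <- c(rep(y[1L], pad), y, rep(y[length(y)], pad))
  as.numeric(stats::filter(ypad, k, sides = 2L))[(pad + 1L):(pad + length(y))]
}

#' Detect peaks in a chromatogram
#'
#' Apexes are local maxima of the (optionally smoothed) trace above
#' `min_height`; peak bounds are placed valley-to-valley: at the lowest
#' point between neighbouring surviving apexes and at the trace minima
#' toward the edges. Prominence is measured as apex height above the higher
#' of the two bounding valleys. Returns an empty table on a flat trace.
#'
#' @param x a `chromatogram`.
#' @param min_height minimum apex height (smoothed scale); default 2% of
#'   the trace maximum.
#' @param min_prominence minimum prominence; default half of `min_height`.
#' @param smooth moving-average window in points (odd; 1 disables
#'   smoothing). Smoothing affects detection only, never integration.
#' @param halfwidth optional maximum half-width in minutes: bounds are
#'   clipped to apex +/- `halfwidth` (the fixed-width fallback; useful on
#'   noisy traces where distant valleys would otherwise pull long stretches
#'   of baseline noise into the integral).
#' @return data.frame with columns `peak_id`, `apex_time`, `left_time`,
#'   `right_time`, `height` (raw intensity at apex), time-ordered and
#'   non-overlapping.
#' @export
detect_peaks <- function(x, min_height = NULL, min_prominence = NULL,
                         smooth = 5L, halfwidth = NULL) {
  stopifnot(inherits(x, "chromatogram"))
  t <- x$times; y <- x$intensities
  ys <- .moving_average(y, smooth)
  n <- length(ys)
  empty <- data.frame(peak_id = integer(0), apex_time = numeric(0),
                      left_time = numeric(0), right_time = numeric(0),
                      height = numeric(0))
  if (n < 3L) return(empty)
  if (is.null(min_height)) min_height <- 0.02 * max(ys)
  if (is.null(min_prominence)) min_prominence <- min_height / 2
  core <- 2:(n - 1L)
  is_max <- ys[core] > ys[core - 1L] & ys[core] >= ys[core + 1L]
  apex <- core[is_max & ys[core] >= min_height]
  if (length(apex) == 0L) return(empty)
  # collapse plateau runs to their first index
  if (length(apex) > 1L) {
    keep <- c(TRUE, diff(apex) > 1L | diff(ys[apex]) != 0)
    apex <- apex[keep]
  }
  bounds_of <- function(apex) {
    k <- length(apex)
    lb <- integer(k); rb <- integer(k)
    for (i in seq_len(k)) {
      lo <- if (i == 1L) 1L else apex[i - 1L]
      hi <- if (i == k) n else apex[i + 1L]
      seg_l <- lo:apex[i]
      seg_r <- apex[i]:hi
      lb[i] <- seg_l[which.min(ys[seg_l])]
      rb[i] <- seg_r[which.min(ys[seg_r])]
    }
    list(lb = lb, rb = rb)
  }
  b <- bounds_of(apex)
  prom <- ys[apex] - pmax(ys[b$lb], ys[b$rb])
  apex <- apex[prom >= min_prominence]
  if (length(apex) == 0L) return(empty)
  b <- bounds_of(apex)  # re-derive valleys between surviving apexes
  left <- t[b$lb]; right <- t[b$rb]
  if (!is.null(halfwidth)) {
    left <- pmax(left, t[apex] - halfwidth)
    right <- pmin(right, t[apex] + halfwidth)
  }
  data.frame(peak_id = seq_along(apex),
             apex_time = t[apex],
             left_time = left,
             right_time = right,
             height = y[apex])
}

#' Integrate a chromatogram between peak bounds
#'
#' Trapezoidal area of the raw trace between `left` and `right`, above
#' either no baseline or a straight line joining the trace values at the
#' two bounds. The result is clipped at zero.
#'
#' @param x a `chromatogram`.
#' @param p a peak: any list/one-row data.frame with `left_time` and
#'   `right_time` (or `left`/`right`) in minutes.
#' @param baseline `"linear"` (default) or `"none"`.
#' @return numeric area in intensity units x minutes.
#' @export
integrate_peak <- function(x, p, baseline = c("linear", "none")) {
  stopifnot(inherits(x, "chromatogram"))
  baseline <- match.arg(baseline)
  left <- p$left_time %||% p$left
  right <- p$right_time %||% p$right
  if (is.null(left) || is.null(right))
    stop("peak must carry left/right bounds", call. = FALSE)
  t <- x$times
  if (left < t[1L] || right > t[length(t)] || left >= right)
    stop("integration bounds [", left, ", ", right,
         "] outside trace domain [", t[1L], ", ", t[length(t)], "]",
         call. = FALSE)
  idx <- which(t >= left & t <= right)
  tt <- t[idx]; yy <- x$intensities[idx]
  if (baseline == "linear" && length(tt) >= 2L) {
    slope <- (yy[length(yy)] - yy[1L]) / (tt[length(tt)] - tt[1L])
    yy <- yy - (yy[1L] + slope * (tt - tt[1L]))
  }
  max(trapezoid(tt, yy), 0)
}

#' Integrate every peak of a peak table
#'
#' @param x a `chromatogram`.
#' @param peaks data.frame from [detect_peaks()].
#' @inheritParams integrate_peak
#' @return `peaks` with an `area` column appended.
#' @export
integrate_peaks <- function(x, peaks, baseline = c("linear", "none")) {
  baseline <- match.arg(baseline)
  peaks$area <- vapply(seq_len(nrow(peaks)), function(i)
    integrate_peak(x, peaks[i, ], baseline = baseline), numeric(1))
  peaks
}

#' Construct a retention-time library
#'
#' @param entries data.frame with columns `label` (canonical linkage
#'   labels), `rt` (minutes), `tolerance` (minutes, > 0) and optionally
#'   `group` (co-elution group id; members of one group share a peak and
#'   must be pairwise symmetric per [is_symmetric_pair()]).
#' @return object of class `rt_library`.
#' @export
rt_library <- function(entries) {
  stopifnot(is.data.frame(entries),
            all(c("label", "rt", "tolerance") %in% names(entries)))
  entries$label <- vapply(entries$label,
                          function(l) parse_linkage(l)$label, character(1))
  if (any(entries$tolerance <= 0))
    stop("retention-time tolerances must be positive", call. = FALSE)
  if (is.null(entries$group)) entries$group <- NA_character_
  for (g in unique(stats::na.omit(entries$group))) {
    members <- entries$label[!is.na(entries$group) & entries$group == g]
    if (length(members) < 2L)
      stop("co-elution group '", g, "' has fewer than 2 members",
           call. = FALSE)
    combs <- utils::combn(members, 2L)
    for (j in seq_len(ncol(combs)))
      if (!is_symmetric_pair(combs[1L, j], combs[2L, j]))
        stop("co-elution group '", g, "' members ", combs[1L, j], " and ",
             combs[2L, j], " are not a symmetric pair", call. = FALSE)
  }
  structure(list(entries = entries), class = "rt_library")
}

#' Read a retention-time library from JSON
#'
#' @param path JSON file with an `entries` array of
#'   `{label, rt, tolerance, group?}` objects.
#' @return an `rt_library`.
#' @export
load_rt_library <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rt_library(as.data.frame(x$entries))
}

#' Default (synthetic) retention-time library
#'
#' Invented, monotone retention times for the PMAAs covered by the package,
#' shipped as editable JSON; carries no claim of matching a real column.
#'
#' @return an `rt_library`.
#' @export
default_rt_library <- function() {
  load_rt_library(system.file("extdata", "rt_library.json",
                              package = "pmaatools", mustWork = TRUE))
}

#' Assign detected peaks to PMAA identities by retention time
#'
#' Each library entry claims the nearest peak within its tolerance. Entries
#' sharing a co-elution group that match the same peak produce one row per
#' member label with a common `shared_group` id, marking a shared peak that
#' must be split from extracted-ion ratios before quantitation. Peaks
#' matched by no entry keep an `NA` label. Two peaks within tolerance of one
#' entry raise an ambiguity error listing the candidates.
#'
#' @param peaks data.frame from [detect_peaks()] (optionally already
#'   integrated).
#' @param lib an [rt_library()].
#' @return data.frame with one row per peak-label assignment: the peak
#'   columns plus `label` and `shared_group`.
#' @export
assign_peaks <- function(peaks, lib) {
  stopifnot(inherits(lib, "rt_library"))
  ent <- lib$entries
  match_of <- rep(NA_integer_, nrow(ent))
  for (i in seq_len(nrow(ent))) {
    dt <- abs(peaks$apex_time - ent$rt[i])
    hits <- which(dt <= ent$tolerance[i])
    if (length(hits) > 1L)
      stop("ambiguous assignment for '", ent$label[i], "': peaks at ",
           paste(sprintf("%.3f", peaks$apex_time[hits]), collapse = ", "),
           " min are all within tolerance", call. = FALSE)
    if (length(hits) == 1L) match_of[i] <- hits
  }
  rows <- list()
  for (p in seq_len(nrow(peaks))) {
    labs <- ent$label[which(match_of == p)]
    grp <- NA_character_
    if (length(labs) == 0L) labs <- NA_character_
    if (length(labs) > 1L) grp <- paste(labs, collapse = "+")
    for (lab in labs) {
      r <- peaks[p, , drop = FALSE]
      r$label <- lab
      r$shared_group <- grp
      rows[[length(rows) + 1L]] <- r
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
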