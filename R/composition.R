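# Roll-ups of linkage tables to monosaccharide and polysaccharide
# compositions, plus diagnostic linkage ratios.

#' Roll a linkage composition up to monosaccharide shares
#'
#' Sums the relative percentages of all linkages of each parent sugar.
#' 3,6-anhydro-galactose counts under galactose unless `split_anhydro` is
#' set, in which case it is reported as its own `AnGal` class (the usual
#' presentation when discussing carrageenan anhydro content).
#'
#' @param t a `composition_table` (or named percentage vector).
#' @param split_anhydro report anhydro-galactose separately.
#' @return named numeric vector of percentages summing to the input total.
#' @export
monosaccharide_rollup <- function(t, split_anhydro = FALSE) {
  v <- if (inherits(t, "composition_table")) composition_values(t) else t
  sugars <- vapply(names(v), function(l) {
    link <- parse_linkage(l)
    if (split_anhydro && has_anhydro(link)) paste0("An", link$sugar)
    else link$sugar
  }, character(1))
  out <- tapply(as.numeric(v), sugars, sum)
  sort(stats::setNames(as.numeric(out), names(out)), decreasing = TRUE)
}

#' Read a linkage-to-polysaccharide assignment table from JSON
#'
#' The assignment table is ordered, user-editable data (not code). Each
#' rule consumes percentage mass from the linkage pool:
#' \describe{
#'   \item{branch_expansion}{Floridean-starch style: one branch-point
#'     linkage per `degree` residues. Consumes the branch label fully plus
#'     `(degree - 1) x branch%` of the backbone label, floored at what the
#'     pool holds.}
#'   \item{pair}{alternating-unit galactan (agarose): `2 x min(a, b)`,
#'     consuming equal shares of both labels; the excess of either unit is
#'     left for later rules.}
#'   \item{sum}{plain total of the listed labels.}
#'   \item{sugar}{every remaining linkage of the listed parent sugars
#'     (optionally including their anhydro forms).}
#' }
#' Whatever remains afterwards lands in the residual bucket.
#'
#' @param path JSON file; see the shipped `assignment_rules.json`.
#' @return object of class `assignment_table`: list with `rules` (ordered
#'   list) and `residual` (bucket name).
#' @export
load_assignment_rules <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  rules <- lapply(x$rules, function(r) {
    r$labels <- unlist(r$labels)
    r$sugars <- unlist(r$sugars)
    r
  })
  structure(list(rules = rules, residual = x$residual %||% "other"),
            class = "assignment_table")
}

#' Default polysaccharide assignment rules
#'
#' Floridean starch (branch expansion on 4,6-Glcp at degree 4.8), agarose
#' (min-pairing of 4-AnGalp and 3-Galp), mixed-linkage xylan, cellulose
#' (remaining 4-Glcp), other galactans (remaining Gal/AnGal), residual
#' bucket `"other"`.
#'
#' @return an `assignment_table`.
#' @export
default_assignment_rules <- function() {
  load_assignment_rules(system.file("extdata", "assignment_rules.json",
                                    package = "pmaatools", mustWork = TRUE))
}

#' Estimate polysaccharide composition from a linkage table
#'
#' Applies the ordered assignment rules against the pool of relative
#' linkage percentages. Every percent consumed by a rule is credited to
#' that rule's polysaccharide, so the output conserves the input total
#' (100%): the residual bucket absorbs whatever no rule claims. Rules whose
#' linkages are entirely absent are skipped with a warning.
#'
#' @param t a `composition_table` (or named percentage vector).
#' @param rules an `assignment_table`; defaults to the shipped rules.
#' @return named numeric vector: percent per polysaccharide (zero-valued
#'   skipped rules omitted), including the residual bucket.
#' @examples
#' estimate_polysaccharides(c("4-AnGalp" = 27, "3-Galp" = 40,
#'                            "4-Glcp" = 33))
#' @export
estimate_polysaccharides <- function(t, rules = default_assignment_rules()) {
  stopifnot(inherits(rules, "assignment_table"))
  pool <- if (inherits(t, "composition_table")) composition_values(t) else t
  total_in <- sum(pool)
  take <- function(label, amount) {
    avail <- if (label %in% names(pool)) pool[[label]] else 0
    got <- min(avail, amount)
    pool[[label]] <<- avail - got
    got
  }
  out <- numeric(0)
  for (rule in rules$rules) {
    value <- switch(
      rule$type,
      branch_expansion = {
        if (!(rule$branch %in% names(pool)) || pool[[rule$branch]] <= 0) {
          warning("rule '", rule$name, "' skipped: branch linkage ",
                  rule$branch, " absent", call. = FALSE)
          NA_real_
        } else {
          x <- take(rule$branch, pool[[rule$branch]])
          x + take(rule$backbone, (rule$degree - 1) * x)
        }
      },
      pair = {
        a <- rule$labels[1L]; b <- rule$labels[2L]
        have <- vapply(c(a, b), function(l)
          l %in% names(pool) && pool[[l]] > 0, logical(1))
        if (!all(have)) {
          warning("rule '", rule$name, "' skipped: ",
                  paste(c(a, b)[!have], collapse = ", "), " absent",
                  call. = FALSE)
          NA_real_
        } else {
          m <- min(pool[[a]], pool[[b]])
          take(a, m) + take(b, m)
        }
      },
      sum = {
        present <- intersect(rule$labels, names(pool)[pool > 0])
        if (length(present) == 0L) {
          warning("rule '", rule$name, "' skipped: no contributing linkage",
                  " present", call. = FALSE)
          NA_real_
        } else {
          sum(vapply(present, function(l) take(l, pool[[l]]), numeric(1)))
        }
      },
      sugar = {
        keep <- vapply(names(pool), function(l) {
          link <- parse_linkage(l)
          link$sugar %in% rule$sugars &&
            (isTRUE(rule$include_anhydro) || !has_anhydro(link))
        }, logical(1))
        present <- names(pool)[keep & pool > 0]
        if (length(present) == 0L) {
          warning("rule '", rule$name, "' skipped: no contributing linkage",
                  " present", call. = FALSE)
          NA_real_
        } else {
          sum(vapply(present, function(l) take(l, pool[[l]]), numeric(1)))
        }
      },
      stop("unknown rule type '", rule$type, "'", call. = FALSE))
    if (!is.na(value)) out[[rule$name]] <- value
  }
  residual <- sum(pool)
  if (residual > 1e-12 || length(out) == 0L) out[[rules$residual]] <- residual
  stopifnot(abs(sum(out) - total_in) < 1e-8)
  out
}

#' Ratio between two linkage percentages
#'
#' Diagnostic ratios such as 4-Xylp : 3-Xylp (mixed-linkage xylan block
#' structure) or 3-Galp : 4-AnGalp (agarose stoichiometry).
#'
#' @param t a `composition_table` (or named percentage vector).
#' @param num_label,den_label numerator and denominator linkage labels.
#' @param digits rounding of the reported ratio (default one decimal, the
#'   conventional presentation); `NULL` for full precision.
#' @return numeric ratio.
#' @examples
#' linkage_ratio(c("4-Xylp" = 54, "3-Xylp" = 18), "4-Xylp", "3-Xylp")  # 3.0
#' @export
linkage_ratio <- function(t, num_label, den_label, digits = 1) {
  v <- if (inherits(t, "composition_table")) composition_values(t) else t
  num_label <- parse_linkage(num_label)$label
  den_label <- parse_linkage(den_label)$label
  den <- if (den_label %in% names(v)) v[[den_label]] else 0
  if (den <= 0)
    stop("undefined ratio: denominator linkage ", den_label,
         " absent or zero", call. = FALSE)
  num <- if (num_label %in% names(v)) v[[num_label]] else 0
  r <- num / den
  if (is.null(digits)) r else round(r, digits)
}
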