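# Chemical model of PMAA derivatives: linkage-code parsing, derivatization
# patterns, nominal masses, symmetric-pair detection, diagnostic EI fragments
# and FID response factors.

# Backbone traits per sugar. `oxygenated` lists the carbons that carry an
# oxygen in the open-chain alditol (deoxy sugars lack O-6).
.sugar_traits <- list(
  Gal = list(n = 6L, oxygenated = 1:6, default_ring = "p"),
  Glc = list(n = 6L, oxygenated = 1:6, default_ring = "p"),
  Man = list(n = 6L, oxygenated = 1:6, default_ring = "p"),
  Xyl = list(n = 5L, oxygenated = 1:5, default_ring = "p"),
  Ara = list(n = 5L, oxygenated = 1:5, default_ring = "f"),
  Rha = list(n = 6L, oxygenated = 1:5, default_ring = "p"),
  Fuc = list(n = 6L, oxygenated = 1:5, default_ring = "p")
)

.atomic_mass <- c(C = 12L, H = 1L, D = 2L, O = 16L)

ring_closure_carbon <- function(ring) if (ring == "p") 5L else 4L

#' Parse a glycosidic linkage shorthand code
#'
#' Parses labels such as `"4-Glcp"`, `"t-Xylp"` or `"2,4-AnGalp"` into a
#' structured linkage description. The grammar is
#' `[t|p1,p2,...]-[An]Sugar[p|f]`: a leading `t` marks a terminal
#' (non-reducing end) residue, otherwise the comma-separated carbon positions
#' are those engaged in glycosidic bonds (for sulfated galactans, positions
#' revealed by sulfate substitution appear here as well, since both block
#' methylation). The optional `An` prefix denotes a 3,6-anhydro bridge
#' (supported on pyranose hexoses only). The trailing ring letter may be
#' omitted, in which case arabinose defaults to furanose and every other
#' sugar to pyranose. Markdown emphasis characters (`*`) are tolerated so
#' labels copied from formatted tables parse unchanged.
#'
#' @param code character scalar linkage label.
#' @return An object of class `linkage_code` with fields `sugar`, `ring`
#'   (`"p"` or `"f"`), `linked_positions` (integer vector, empty for
#'   terminal), `anhydro_bridge` (integer vector `c(3, 6)` or `NULL`) and
#'   `label` (the canonical string form; `format()` returns it).
#' @examples
#' parse_linkage("2,4-AnGalp")
#' format(parse_linkage("t-Xyl*p*"))
#' @export
parse_linkage <- function(code) {
  if (inherits(code, "linkage_code")) return(code)
  stopifnot(is.character(code), length(code) == 1L)
  raw <- gsub("[*[:space:]]", "", code)
  m <- regexec("^(t|[2-9](?:,[2-9])*)-(An)?(Gal|Glc|Xyl|Man|Ara|Rha|Fuc)(p|f)?$",
               raw)
  parts <- regmatches(raw, m)[[1L]]
  if (length(parts) == 0L) {
    stop("cannot parse linkage code '", code,
         "': expected '[t|p1,p2,...]-[An]Sugar[p|f]' with a known sugar token",
         call. = FALSE)
  }
  pos_tok <- parts[2L]
  anhydro <- parts[3L] == "An"
  sugar <- parts[4L]
  ring <- parts[5L]
  traits <- .sugar_traits[[sugar]]
  if (ring == "") ring <- traits$default_ring
  linked <- if (pos_tok == "t") integer(0) else
    sort(unique(as.integer(strsplit(pos_tok, ",", fixed = TRUE)[[1L]])))

  max_linkable <- max(traits$oxygenated)
  if (length(linked) && any(linked > max_linkable)) {
    bad <- linked[linked > max_linkable][1L]
    stop("position ", bad, " out of range for ", sugar,
         " in linkage code '", code, "'", call. = FALSE)
  }
  ring_c <- ring_closure_carbon(ring)
  if (ring_c %in% linked) {
    stop("position ", ring_c, " is the ring-closure carbon of a ",
         if (ring == "p") "pyranose" else "furanose",
         " and cannot carry a glycosidic bond ('", code, "')", call. = FALSE)
  }
  bridge <- NULL
  if (anhydro) {
    if (traits$n != 6L || length(traits$oxygenated) != 6L)
      stop("anhydro bridge is only supported on hexoses ('", code, "')",
           call. = FALSE)
    if (ring != "p")
      stop("3,6-anhydro bridge requires the pyranose ring form ('", code,
           "')", call. = FALSE)
    bridge <- c(3L, 6L)
    clash <- intersect(bridge, linked)
    if (length(clash))
      stop("anhydro position ", clash[1L],
           " collides with a linked position in '", code, "'", call. = FALSE)
  }
  out <- structure(
    list(sugar = sugar, ring = ring, linked_positions = linked,
         anhydro_bridge = bridge),
    class = "linkage_code")
  out$label <- format(out)
  out
}

#' @export
format.linkage_code <- function(x, ...) {
  pos <- if (length(x$linked_positions) == 0L) "t" else
    paste(x$linked_positions, collapse = ",")
  paste0(pos, "-", if (!is.null(x$anhydro_bridge)) "An" else "",
         x$sugar, x$ring)
}

#' @export
print.linkage_code <- function(x, ...) {
  cat("<linkage_code> ", x$label, "\n", sep = "")
  invisible(x)
}

is_terminal <- function(link) length(link$linked_positions) == 0L
has_anhydro <- function(link) !is.null(link$anhydro_bridge)

#' Derive the PMAA substitution pattern and mass of a linkage
#'
#' Models the methylation-analysis derivatization chain: permethylation of
#' free hydroxyls, depolymerization, reduction of C-1 (by borodeuteride in
#' the standard route, or by the non-deuterating amine borane used in the
#' reductive-hydrolysis route that preserves 3,6-anhydro-galactose), and
#' peracetylation of every hydroxyl exposed by hydrolysis. Acetyl groups
#' therefore mark C-1, the ring-closure carbon, and every glycosidically
#' linked (or sulfated) position; all remaining oxygen-bearing carbons carry
#' methyl ethers, except those fused into an anhydro bridge.
#'
#' Masses are nominal (integer) sums over the atomic composition of the
#' open-chain partially methylated alditol acetate.
#'
#' @param link a `linkage_code` or a label parseable by [parse_linkage()].
#' @param deuterate logical; `TRUE` adds the C-1 deuterium introduced by
#'   NaBD4 reduction. Must be `FALSE` for anhydro linkages, whose alditols
#'   come from the non-deuterating reductive-hydrolysis route.
#' @return An object of class `pmaa_derivative` with fields `source`,
#'   `acetyl_positions`, `methyl_positions`, `anhydro_positions`,
#'   `deuterated_c1`, `formula` (named integer vector over C/H/D/O) and
#'   `nominal_mass`.
#' @examples
#' derivatize("4-Glcp", deuterate = TRUE)$nominal_mass  # 351
#' derivatize("4-AnGalp")$methyl_positions              # C-2 only
#' @export
derivatize <- function(link, deuterate = FALSE) {
  link <- parse_linkage(link)
  if (deuterate && has_anhydro(link))
    stop("deuteration is not available for anhydro linkage '", link$label,
         "': the anhydro-preserving reductive hydrolysis uses a",
         " non-deuterating reductant", call. = FALSE)
  traits <- .sugar_traits[[link$sugar]]
  anhydro <- link$anhydro_bridge %||% integer(0)
  acetyl <- sort(unique(c(1L, ring_closure_carbon(link$ring),
                          link$linked_positions)))
  methyl <- setdiff(traits$oxygenated, c(acetyl, anhydro))
  n <- traits$n
  n_ac <- length(acetyl); n_me <- length(methyl)
  bridge <- length(anhydro) > 0L
  formula <- c(
    C = n + n_me + 2L * n_ac,
    H = (2L * n + 2L) + 2L * n_me + 2L * n_ac - (if (bridge) 2L else 0L) -
      (if (deuterate) 1L else 0L),
    D = if (deuterate) 1L else 0L,
    O = length(traits$oxygenated) + n_ac - (if (bridge) 1L else 0L))
  structure(
    list(source = link,
         acetyl_positions = acetyl,
         methyl_positions = methyl,
         anhydro_positions = anhydro,
         deuterated_c1 = deuterate,
         formula = formula,
         nominal_mass = sum(formula * .atomic_mass[names(formula)])),
    class = "pmaa_derivative")
}

#' @export
print.pmaa_derivative <- function(x, ...) {
  cat("<pmaa_derivative> ", x$source$label,
      if (x$deuterated_c1) " (C-1 d)" else "",
      "\n  acetyl: ", paste(x$acetyl_positions, collapse = ","),
      "  methyl: ", paste(x$methyl_positions, collapse = ","),
      if (length(x$anhydro_positions))
        paste0("  anhydro: ", paste(x$anhydro_positions, collapse = ",")),
      "\n  nominal mass: ", x$nominal_mass, " Da\n", sep = "")
  invisible(x)
}

#' Nominal mass of the PMAA derivative of a linkage
#'
#' Convenience wrapper around [derivatize()]. By default the mass follows
#' the preparation route actually used per linkage class: C-1 deuterated for
#' non-anhydro linkages (TFA hydrolysis + NaBD4), non-deuterated for anhydro
#' linkages (reductive hydrolysis).
#'
#' @param link linkage label or `linkage_code`.
#' @param deuterate logical or `NA`; `NA` selects the route-appropriate
#'   default described above.
#' @return integer nominal mass in Da.
#' @export
pmaa_mass <- function(link, deuterate = NA) {
  link <- parse_linkage(link)
  if (is.na(deuterate)) deuterate <- !has_anhydro(link)
  derivatize(link, deuterate = deuterate)$nominal_mass
}

# Per-carbon substituent classes of the non-deuterated PMAA, positions 1..n.
.substituent_pattern <- function(link) {
  d <- derivatize(link, deuterate = FALSE)
  n <- .sugar_traits[[link$sugar]]$n
  sub <- rep("H", n)
  sub[d$acetyl_positions] <- "OAc"
  sub[d$methyl_positions] <- "OMe"
  if (length(d$anhydro_positions)) sub[d$anhydro_positions] <- "An"
  sub
}

#' Test whether two linkages give chromatographically indistinguishable PMAAs
#'
#' Two non-anhydro linkages of the same sugar and ring form yield the same
#' PMAA molecule (up to the position of the C-1 deuterium label) when the
#' substitution pattern of one maps onto the other under reversal of the
#' alditol chain (position i to n+1-i). Such pairs, e.g. 2-Xylp/4-Xylp and
#' 2,3,6-Galp/2,4,6-Galp, co-elute and share one GC peak; only the deuterium
#' label placed at C-1 breaks the symmetry in EI-MS.
#'
#' @param a,b linkage labels or `linkage_code` objects.
#' @return logical flag.
#' @examples
#' is_symmetric_pair("2-Xylp", "4-Xylp")        # TRUE
#' is_symmetric_pair("3-Galp", "4-Galp")        # FALSE
#' @export
is_symmetric_pair <- function(a, b) {
  a <- parse_linkage(a); b <- parse_linkage(b)
  if (a$sugar != b$sugar || a$ring != b$ring) return(FALSE)
  if (has_anhydro(a) || has_anhydro(b)) return(FALSE)
  identical(rev(.substituent_pattern(a)), .substituent_pattern(b))
}

# Mass contribution of one backbone carbon with its substituent, as part of
# a primary EI fragment (even-electron cation; plain atom sum).
.carbon_contrib <- function(position, n, sub, deuterated) {
  h <- if (position %in% c(1L, n)) 2L else 1L
  base <- 12L + h
  if (position == 1L && deuterated) base <- base + 1L  # one H is D
  base + switch(sub,
                OAc = 59L,  # O-C(=O)-CH3
                OMe = 31L,  # O-CH3
                H   = 1L)   # deoxy carbon: extra H instead of O-substituent
}

#' Predict primary EI-MS fragments of a PMAA derivative
#'
#' Enumerates the primary fragments produced by a single cleavage of one
#' backbone C-C bond, with the charge retained on either side. The retained
#' side is the contiguous carbon run containing C-1 or Cn; its mass is the
#' integer sum of the backbone carbons with their hydrogens and O-methyl /
#' O-acetyl substituents as an even-electron cation. Fragments containing
#' C-1 carry the +1 deuterium shift when the derivative is labeled. This
#' single-cleavage approximation (no secondary losses of acetic acid or
#' methanol) is intended to select label-discriminating diagnostic ions for
#' symmetric pairs, not to simulate full spectra.
#'
#' @param d a `pmaa_derivative` (non-anhydro), or a linkage label which is
#'   derivatized with deuteration.
#' @return data.frame with columns `mz` (integer), `side` (`"C1"` or
#'   `"Cn"`), `carbons` (retained run, e.g. `"1-2"`) and `cleavage` (index
#'   of the broken bond, between carbon `cleavage` and `cleavage + 1`).
#' @examples
#' predict_fragments(derivatize("4-Xylp", deuterate = TRUE))
#' @export
predict_fragments <- function(d) {
  if (!inherits(d, "pmaa_derivative")) d <- derivatize(d, deuterate = TRUE)
  if (length(d$anhydro_positions))
    stop("fragment prediction is unsupported for anhydro derivative '",
         d$source$label, "': the bicyclic system does not follow simple",
         " chain cleavage", call. = FALSE)
  link <- d$source
  n <- .sugar_traits[[link$sugar]]$n
  sub <- .substituent_pattern(link)
  contrib <- vapply(seq_len(n), function(i)
    .carbon_contrib(i, n, sub[i], d$deuterated_c1), integer(1))
  rows <- lapply(seq_len(n - 1L), function(cut) {
    data.frame(
      mz = c(sum(contrib[seq_len(cut)]), sum(contrib[(cut + 1L):n])),
      side = c("C1", "Cn"),
      carbons = c(paste0("1-", cut), paste0(cut + 1L, "-", n)),
      cleavage = cut,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$mz), , drop = FALSE]
}

#' Choose diagnostic EI ions for a co-eluting symmetric PMAA pair
#'
#' For a symmetric pair whose C-1 deuterated derivatives differ only in
#' which side of the chain carries the label, picks one label-bearing
#' (C-1-containing) fragment mass unique to each member, maximizing the m/z
#' separation between the two chosen ions (ties broken toward higher
#' masses). Extracted-ion chromatograms at these masses quantify the molar
#' ratio within the shared GC peak.
#'
#' @param a,b the two linkage labels (must satisfy [is_symmetric_pair()]).
#' @return named integer vector of length 2 (names are the canonical
#'   labels), the diagnostic m/z of each member.
#' @examples
#' diagnostic_ions("2-Xylp", "4-Xylp")
#' @export
diagnostic_ions <- function(a, b) {
  a <- parse_linkage(a); b <- parse_linkage(b)
  if (!is_symmetric_pair(a, b))
    stop("'", a$label, "' and '", b$label, "' are not a symmetric pair",
         call. = FALSE)
  fa <- predict_fragments(derivatize(a, deuterate = TRUE))
  fb <- predict_fragments(derivatize(b, deuterate = TRUE))
  ua <- setdiff(fa$mz[fa$side == "C1"], fb$mz)
  ub <- setdiff(fb$mz[fb$side == "C1"], fa$mz)
  if (length(ua) == 0L || length(ub) == 0L)
    stop("no label-discriminating fragments found for pair ", a$label, " / ",
         b$label, call. = FALSE)
  grid <- expand.grid(ma = ua, mb = ub)
  grid <- grid[order(-abs(grid$ma - grid$mb), -pmax(grid$ma, grid$mb)), ]
  out <- c(grid$ma[1L], grid$mb[1L])
  names(out) <- c(a$label, b$label)
  out
}

#' Construct a FID response-factor library
#'
#' Relative molar FID response factors for PMAAs, following the effective
#' carbon number (ECN) concept: the FID signal per mole scales with the
#' number of carbons effectively combusted, so factors are dimensionless
#' ratios against a reference derivative. Quantitation divides peak area by
#' the factor, so under-responding derivatives (notably 3,6-anhydro-sugar
#' PMAAs, which also suffer partial degradation during harsh permethylation)
#' receive a boosted molar share.
#'
#' @param entries named numeric vector, canonical label -> factor. All
#'   factors must lie in (0, 2].
#' @param increment_rules list of rules, each `list(position =, delta =)`:
#'   a derivative whose label is not in `entries` but differs from a present
#'   label only by an additional linked position `position` (an
#'   acetyl-for-methyl swap at that carbon) takes the base factor plus
#'   `delta`. The default library ships the O-2 rule with delta +0.05.
#' @return object of class `response_factor_library`.
#' @export
response_factor_library <- function(entries, increment_rules = list()) {
  stopifnot(is.numeric(entries), !is.null(names(entries)))
  if (any(entries <= 0 | entries > 2))
    stop("response factors must lie in (0, 2]", call. = FALSE)
  names(entries) <- vapply(names(entries),
                           function(l) parse_linkage(l)$label, character(1))
  structure(list(entries = entries, increment_rules = increment_rules),
            class = "response_factor_library")
}

#' Read a response-factor library from JSON
#'
#' Expects an object with an `entries` map (label -> factor) and an optional
#' `increment_rules` array of `{position, delta}` objects.
#'
#' @param path path to a JSON file.
#' @return a `response_factor_library`.
#' @export
load_response_factors <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rules <- list()
  if (!is.null(x$increment_rules)) {
    rl <- x$increment_rules
    rules <- lapply(seq_len(nrow(rl)), function(i)
      list(position = as.integer(rl$position[i]), delta = rl$delta[i]))
  }
  response_factor_library(unlist(x$entries), rules)
}

#' Default FID response-factor library
#'
#' Curated table shipped with the package: ECN-derived factors for
#' non-anhydro PMAAs (keyed by canonical label), the experimentally anchored
#' values 0.74 for 3-Galp and 0.49 for 4-AnGalp (from an equimolar agarose
#' standard), 0.54 for 2,4-AnGalp, and the O-2 acetyl-for-methyl increment
#' rule (+0.05).
#'
#' @return a `response_factor_library`.
#' @export
default_response_factors <- function() {
  load_response_factors(system.file("extdata", "response_factors.json",
                                    package = "pmaatools", mustWork = TRUE))
}

#' Look up the FID response factor of a PMAA
#'
#' Returns the library entry for the derivative's canonical label, or, when
#' absent, derives one by applying an increment rule at most once per
#' substituted position: if dropping a linked position from the label yields
#' a library entry and a rule covers that position, the factor is the base
#' entry plus the rule's delta. Unknown PMAAs fail loudly; there is no
#' silent default of 1.0, since unit factors would bias compositions.
#'
#' @param d a `pmaa_derivative`, `linkage_code` or label.
#' @param lib a `response_factor_library`.
#' @return numeric factor.
#' @examples
#' response_factor("3-Galp", default_response_factors())   # 0.74
#' response_factor("2,4-AnGalp", default_response_factors())
#' @export
response_factor <- function(d, lib) {
  stopifnot(inherits(lib, "response_factor_library"))
  link <- if (inherits(d, "pmaa_derivative")) d$source else parse_linkage(d)
  label <- link$label
  if (label %in% names(lib$entries)) return(unname(lib$entries[[label]]))
  for (rule in lib$increment_rules) {
    pos <- rule$position
    if (!(pos %in% link$linked_positions)) next
    base <- link
    base$linked_positions <- setdiff(base$linked_positions, pos)
    base$label <- format(base)
    if (base$label %in% names(lib$entries))
      return(unname(lib$entries[[base$label]]) + rule$delta)
  }
  stop("no response factor for '", label,
       "' and no applicable increment rule", call. = FALSE)
}
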