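#' Assay configuration: fragments, STR loci, dyes and thresholds
#'
#' The multiplex assay is described declaratively: every fixed restriction
#' fragment the caller may encounter (wild-type, variant, uncut and control
#' products), the two STR loci used for identity monitoring, the dye channel
#' each product is labelled with, and all interpretation thresholds. The
#' caller and the simulator share one configuration object so that simulated
#' and interpreted peak positions can never drift apart.
#'
#' @name assay_config
NULL

# canonical dye channels (colour words as seen on the electropherogram)
.DYES <- c("blue", "green", "black", "red", "orange")

# fluorochrome -> channel colour mapping used by the default assay
.FLUOR_TO_DYE <- c("PET" = "red", "6-FAM" = "blue", "VIC" = "green", "NED" = "black")

#' Define one fixed restriction fragment
#'
#' @param locus Locus identifier, e.g. `"F5"`, `"F2"`, `"HIND_CTRL"`.
#' @param allele One of `"wt"`, `"variant"`, `"uncut"`, `"control_cut"`,
#'   `"control_uncut"`. The two uncut labels mark fragments that must be
#'   completely absent after digestion; their persistence flags a digestion
#'   failure.
#' @param size Apparent size in bp on the capillary instrument.
#' @param dye Channel colour, one of blue/green/black/red/orange.
#' @param must_be_absent_after_digestion Logical; `TRUE` exactly for the
#'   uncut products.
#' @return A `fragment_rule` list.
#' @export
fragment_rule <- function(locus, allele, size, dye,
                          must_be_absent_after_digestion = FALSE) {
  allele <- match.arg(allele,
                      c("wt", "variant", "uncut", "control_cut", "control_uncut"))
  dye <- match.arg(dye, .DYES)
  size <- as.numeric(size)
  if (!is.finite(size) || size <= 0)
    stop("fragment_rule: apparent size must be a positive number (locus ",
         locus, ")", call. = FALSE)
  structure(list(locus = as.character(locus), allele = allele,
                 size = size, dye = dye,
                 must_be_absent_after_digestion =
                   isTRUE(must_be_absent_after_digestion)),
            class = "fragment_rule")
}

#' Convert an STR allele label to its numeric repeat value
#'
#' Microvariant alleles follow the forensic convention `n.p` where `p` in
#' 1..3 counts extra bases beyond `n` full tetranucleotide repeats, so
#' `"22.2"` is 22 repeats plus 2 bases = 22.5 repeat units.
#'
#' @param label Character allele label(s), e.g. `"22"` or `"22.2"`.
#' @return Numeric repeat value(s).
#' @export
allele_value <- function(label) {
  vapply(as.character(label), function(x) {
    parts <- strsplit(x, ".", fixed = TRUE)[[1]]
    whole <- as.numeric(parts[1])
    partial <- if (length(parts) > 1) as.numeric(parts[2]) else 0
    if (is.na(whole) || is.na(partial) || !partial %in% 0:3)
      stop("invalid STR allele label: ", x, call. = FALSE)
    whole + partial / 4
  }, numeric(1), USE.NAMES = FALSE)
}

#' Convert a numeric repeat value to its allele label
#'
#' @param value Numeric repeat value(s) on the quarter-repeat lattice.
#' @return Character label(s) in forensic `n` / `n.p` notation.
#' @export
allele_label <- function(value) {
  vapply(value, function(v) {
    whole <- floor(v + 1e-9)
    partial <- round((v - whole) * 4)
    if (partial == 4) { whole <- whole + 1; partial <- 0 }
    if (partial == 0) as.character(whole) else paste0(whole, ".", partial)
  }, character(1))
}

#' Define an STR locus
#'
#' The allele ladder is a linear map from repeat count to apparent size,
#' anchored at the smallest ladder allele: `size(r) = size_at_min_repeats +
#' repeat_unit * (r - min_repeats)` with `r` in repeat units (microvariants
#' count as quarter repeats for a 4 bp unit). The observed size range is the
#' image of the ladder endpoints under this map.
#'
#' @param locus Locus identifier (`"FGA"` or `"SE33"` in the default assay).
#' @param dye Channel colour.
#' @param repeat_unit Repeat unit length in bp (4 for tetranucleotide loci).
#' @param min_repeats,max_repeats Smallest and largest ladder allele, as
#'   labels (e.g. `"14"`, `"50.2"`).
#' @param size_at_min_repeats Apparent size in bp of the smallest allele.
#' @return An `str_locus` list with computed `observed_size_min/max`.
#' @export
str_locus <- function(locus, dye, repeat_unit, min_repeats, max_repeats,
                      size_at_min_repeats) {
  dye <- match.arg(dye, .DYES)
  repeat_unit <- as.integer(repeat_unit)
  min_v <- allele_value(min_repeats)
  max_v <- allele_value(max_repeats)
  if (min_v >= max_v)
    stop("str_locus: min_repeats must be below max_repeats", call. = FALSE)
  obj <- structure(list(
    locus = as.character(locus), dye = dye, repeat_unit = repeat_unit,
    min_repeats = as.character(min_repeats),
    max_repeats = as.character(max_repeats),
    min_value = min_v, max_value = max_v,
    size_at_min_repeats = as.numeric(size_at_min_repeats)), class = "str_locus")
  obj$observed_size_min <- obj$size_at_min_repeats
  obj$observed_size_max <- str_repeats_to_size(obj, max_repeats)
  obj
}

#' Enumerate the full allele ladder of an STR locus
#'
#' @param locus An `str_locus`.
#' @return Character vector of all ladder allele labels (1 bp spacing).
#' @export
str_ladder <- function(locus) {
  vals <- seq(locus$min_value, locus$max_value + 1e-9, by = 1 / locus$repeat_unit)
  allele_label(vals)
}

#' Map an STR allele to its apparent size
#'
#' Exact inverse of [str_size_to_repeats()] on the ladder.
#'
#' @param locus An `str_locus`.
#' @param allele Allele label(s) or numeric repeat value(s).
#' @return Apparent size(s) in bp.
#' @export
str_repeats_to_size <- function(locus, allele) {
  v <- if (is.numeric(allele)) allele else allele_value(allele)
  locus$size_at_min_repeats + locus$repeat_unit * (v - locus$min_value)
}

#' Bin an apparent size to the nearest ladder allele
#'
#' Sizes outside the locus's observed range (plus tolerance) are reported as
#' off-ladder rather than raising an error: real contaminant or artifact
#' peaks can land anywhere and the caller must keep going.
#'
#' @param locus An `str_locus`.
#' @param size Apparent size in bp.
#' @param tol Binning tolerance in bp (default 0.5, single-base resolution).
#' @return List with `label` (allele label or `NA` if off-ladder), `value`
#'   (numeric repeats), `size` (exact ladder size) and `off_ladder` flag.
#' @export
str_size_to_repeats <- function(locus, size, tol = 0.5) {
  if (size < locus$observed_size_min - tol ||
      size > locus$observed_size_max + tol) {
    return(list(label = NA_character_, value = NA_real_,
                size = NA_real_, off_ladder = TRUE))
  }
  offset_bp <- round(size - locus$size_at_min_repeats)
  offset_bp <- max(0, min(offset_bp,
                          round((locus$max_value - locus$min_value) *
                                locus$repeat_unit)))
  value <- locus$min_value + offset_bp / locus$repeat_unit
  list(label = allele_label(value), value = value,
       size = locus$size_at_min_repeats + offset_bp, off_ladder = FALSE)
}

#' Interpretation thresholds
#'
#' @param allele_call_rfu Minimum peak height (RFU) for allele calling;
#'   default 150, three times the background noise ceiling.
#' @param noise_ceiling_rfu Highest background peak seen in blank runs (50).
#' @param saturation_rfu Instrument saturation ceiling (32000).
#' @param stutter_max_fraction Largest height fraction of its parent allele a
#'   peak one repeat short may have and still be accepted as stutter (0.11 =
#'   stutter mean + 2 SD).
#' @param het_ratio_min_f5,het_ratio_min_f2 Lower bound on the variant/wt
#'   peak-height ratio of a heterozygote before a re-test is required (0.49 =
#'   mean - 2 SD for both loci).
#' @param size_match_tol Matching tolerance in bp for fixed fragments (1.0).
#' @param str_bin_tol Binning tolerance in bp for STR alleles (0.5).
#' @param str_second_allele_min Minimum height fraction of the tallest STR
#'   peak for a second peak to be accepted as a true sister allele; below it
#'   (and above the stutter ceiling) the peak is treated as an unexplained
#'   extra, the signature of contaminating DNA.
#' @param stutter_k SD multiplier behind the stutter ceiling (2).
#' @return A `thresholds` list.
#' @export
thresholds <- function(allele_call_rfu = 150, noise_ceiling_rfu = 50,
                       saturation_rfu = 32000, stutter_max_fraction = 0.11,
                       het_ratio_min_f5 = 0.49, het_ratio_min_f2 = 0.49,
                       size_match_tol = 1.0, str_bin_tol = 0.5,
                       str_second_allele_min = 0.5, stutter_k = 2) {
  th <- list(allele_call_rfu = allele_call_rfu,
             noise_ceiling_rfu = noise_ceiling_rfu,
             saturation_rfu = saturation_rfu,
             stutter_max_fraction = stutter_max_fraction,
             het_ratio_min_f5 = het_ratio_min_f5,
             het_ratio_min_f2 = het_ratio_min_f2,
             size_match_tol = size_match_tol,
             str_bin_tol = str_bin_tol,
             str_second_allele_min = str_second_allele_min,
             stutter_k = stutter_k)
  stopifnot(th$stutter_max_fraction > 0, th$stutter_max_fraction < 1,
            th$het_ratio_min_f5 > 0, th$het_ratio_min_f5 < 1,
            th$het_ratio_min_f2 > 0, th$het_ratio_min_f2 < 1,
            th$allele_call_rfu > 0, th$size_match_tol > 0)
  structure(th, class = "thresholds")
}

#' Assemble and validate a full assay configuration
#'
#' @param fragments List of [fragment_rule()]s.
#' @param str_loci List of [str_locus()] definitions.
#' @param thresholds A [thresholds()] object.
#' @param dyes Named character vector mapping fluorochrome names to channel
#'   colours (metadata; calling works on channel colours).
#' @return An `assay_config` object.
#' @export
assay_config <- function(fragments, str_loci, thresholds = rflpmx::thresholds(),
                         dyes = .FLUOR_TO_DYE) {
  cfg <- structure(list(fragments = fragments, str_loci = str_loci,
                        thresholds = thresholds, dyes = dyes),
                   class = "assay_config")
  validate_assay_config(cfg)
  cfg
}

#' Validate an assay configuration
#'
#' Checks the structural invariants: positive sizes, the equivalence of the
#' must-be-absent flag with the uncut allele labels, and that no two fixed
#' fragments collide on the same dye within the size-matching tolerance.
#'
#' @param cfg An `assay_config`.
#' @return `cfg`, invisibly; stops with a descriptive error on violation.
#' @export
validate_assay_config <- function(cfg) {
  fr <- cfg$fragments
  for (r in fr) {
    uncut <- r$allele %in% c("uncut", "control_uncut")
    if (uncut != r$must_be_absent_after_digestion)
      stop("config invariant violated: fragment ", r$locus, "/", r$allele,
           " must_be_absent_after_digestion flag must equal (allele is uncut)",
           call. = FALSE)
  }
  tol <- cfg$thresholds$size_match_tol
  key <- data.frame(dye = vapply(fr, `[[`, "", "dye"),
                    size = vapply(fr, `[[`, 0, "size"))
  for (d in unique(key$dye)) {
    s <- sort(key$size[key$dye == d])
    if (length(s) > 1 && any(diff(s) <= tol))
      stop("config invariant violated: two fragments on dye '", d,
           "' are closer than the size tolerance (", tol, " bp)",
           call. = FALSE)
  }
  lids <- vapply(cfg$str_loci, `[[`, "", "locus")
  if (anyDuplicated(lids))
    stop("config invariant violated: duplicated STR locus id", call. = FALSE)
  invisible(cfg)
}

.cfg_to_list <- function(cfg) {
  list(
    fragments = lapply(cfg$fragments, function(r)
      list(locus = r$locus, allele = r$allele, size = r$size, dye = r$dye,
           must_be_absent_after_digestion = r$must_be_absent_after_digestion)),
    str_loci = lapply(cfg$str_loci, function(l)
      list(locus = l$locus, dye = l$dye, repeat_unit = l$repeat_unit,
           min_repeats = l$min_repeats, max_repeats = l$max_repeats,
           size_at_min_repeats = l$size_at_min_repeats)),
    thresholds = unclass(cfg$thresholds),
    dyes = as.list(cfg$dyes))
}

#' Read an assay configuration from a YAML file
#'
#' @param path Path to a YAML file with top-level keys `fragments`,
#'   `str_loci`, `thresholds`, `dyes`.
#' @return A validated `assay_config`.
#' @export
load_assay_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  for (k in c("fragments", "str_loci", "thresholds"))
    if (is.null(raw[[k]]))
      stop("config parse error: missing top-level field '", k, "'",
           call. = FALSE)
  frags <- lapply(raw$fragments, function(r) {
    for (k in c("locus", "allele", "size", "dye"))
      if (is.null(r[[k]]))
        stop("config parse error: fragment entry missing field '", k, "'",
             call. = FALSE)
    fragment_rule(r$locus, r$allele, r$size, r$dye,
                  isTRUE(r$must_be_absent_after_digestion))
  })
  loci <- lapply(raw$str_loci, function(l) {
    for (k in c("locus", "dye", "repeat_unit", "min_repeats", "max_repeats",
                "size_at_min_repeats"))
      if (is.null(l[[k]]))
        stop("config parse error: str_locus entry missing field '", k, "'",
             call. = FALSE)
    str_locus(l$locus, l$dye, l$repeat_unit, as.character(l$min_repeats),
              as.character(l$max_repeats), l$size_at_min_repeats)
  })
  th <- do.call(thresholds, raw$thresholds)
  dyes <- unlist(raw$dyes)
  assay_config(frags, loci, th, dyes)
}

#' Write an assay configuration to YAML
#'
#' Round-trips with [load_assay_config()].
#'
#' @param cfg An `assay_config`.
#' @param path Output path.
#' @export
write_assay_config <- function(cfg, path) {
  yaml::write_yaml(.cfg_to_list(cfg), path)
  invisible(path)
}

#' The packaged default assay configuration
#'
#' Fixed fragments: F5 wt 92 / variant 129 / uncut 289 bp on the red (PET)
#' channel; F2 wt 246 / variant 226 bp on red; HindIII digestion-control cut
#' 276 / uncut 339 bp on black (NED). STR loci: FGA (green/VIC, alleles
#' 14–50.2) and SE33 (blue/6-FAM, alleles 4.2–39), tetranucleotide repeats.
#' Thresholds: 150 RFU allele calling (3x the 50 RFU noise ceiling), 0.49
#' heterozygous ratio floor for both loci, 11% stutter ceiling, 32000 RFU
#' saturation.
#'
#' @return A validated `assay_config`.
#' @export
default_assay_config <- function() {
  path <- system.file("extdata", "default_assay.yaml", package = "rflpmx")
  load_assay_config(path)
}

# lookup helpers used across modules -----------------------------------------

.frag <- function(cfg, locus, allele) {
  for (r in cfg$fragments)
    if (r$locus == locus && r$allele == allele) return(r)
  stop("no fragment rule for ", locus, "/", allele, call. = FALSE)
}

.str_locus <- function(cfg, locus) {
  for (l in cfg$str_loci) if (l$locus == locus) return(l)
  stop("no STR locus '", locus, "' in config", call. = FALSE)
}

#' @export
print.assay_config <- function(x, ...) {
  cat("Multiplex PCR-RFLP assay configuration\n")
  cat(sprintf("  %d fixed fragments, %d STR loci\n",
              length(x$fragments), length(x$str_loci)))
  for (r in x$fragments)
    cat(sprintf("    %-10s %-14s %6.1f bp  %s%s\n", r$locus, r$allele, r$size,
                r$dye,
                if (r$must_be_absent_after_digestion) "  [must vanish]" else ""))
  for (l in x$str_loci)
    cat(sprintf("    %-10s STR %s-%s repeats  %.0f-%.1f bp  %s\n", l$locus,
                l$min_repeats, l$max_repeats, l$observed_size_min,
                l$observed_size_max, l$dye))
  cat(sprintf("  calling threshold %g RFU, stutter ceiling %g, het ratio floor %g/%g\n",
              x$thresholds$allele_call_rfu, x$thresholds$stutter_max_fraction,
              x$thresholds$het_ratio_min_f5, x$thresholds$het_ratio_min_f2))
  invisible(x)
}
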