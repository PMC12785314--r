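#' Contamination assessment, identity matching and random-match probability
#'
#' Cross-sample quality layer built on the dual-STR design. Contaminating
#' DNA betrays itself in one of three ways: an additional STR allele, a
#' stutter-position peak exceeding the expected stutter ceiling, or an
#' abnormal variant/wt peak-height ratio at F5 or F2. A contaminant sharing
#' all four STR alleles (or their stutter positions) with the host sample is
#' undetectable by design — a documented blind spot, mitigated by the ratio
#' criterion.
#'
#' @name contamination
NULL

#' Apply the three contamination criteria to a sample report
#'
#' @param report A `sample_report` from [call_sample()].
#' @param cfg An `assay_config`.
#' @return A `contamination_verdict`: `detected`, `criteria_hit` (subset of
#'   `EXTRA_ALLELE`, `STUTTER_EXCESS`, `RATIO_IMBALANCE`) and an `evidence`
#'   data frame (locus, size, height, explanation).
#' @export
assess_contamination <- function(report, cfg = default_assay_config()) {
  criteria <- character()
  ev <- data.frame(locus = character(), size = numeric(), height = numeric(),
                   explanation = character())
  for (sc in report$strs) {
    if (nrow(sc$extras)) {
      stut <- !is.na(sc$extras$parent_allele)
      if (any(!stut)) {
        criteria <- c(criteria, "EXTRA_ALLELE")
        ev <- rbind(ev, data.frame(
          locus = sc$locus, size = sc$extras$size[!stut],
          height = sc$extras$height[!stut],
          explanation = "unexplained STR peak"))
      }
      if (any(stut)) {
        criteria <- c(criteria, "STUTTER_EXCESS")
        ev <- rbind(ev, data.frame(
          locus = sc$locus, size = sc$extras$size[stut],
          height = sc$extras$height[stut],
          explanation = sprintf("stutter-position peak at %.1f%% of parent (ceiling %.0f%%)",
                                100 * sc$extras$fraction[stut],
                                100 * cfg$thresholds$stutter_max_fraction)))
      }
    }
    if (nrow(sc$off_ladder)) {
      criteria <- c(criteria, "EXTRA_ALLELE")
      ev <- rbind(ev, data.frame(
        locus = sc$locus, size = sc$off_ladder$size,
        height = sc$off_ladder$height, explanation = "off-ladder STR peak"))
    }
  }
  # ratio imbalance is delegated to the caller's 0.49 flags, not recomputed
  for (loc in c("F5", "F2")) {
    if (paste0("RATIO_LOW_", loc) %in% report$qc_flags) {
      criteria <- c(criteria, "RATIO_IMBALANCE")
      bc <- if (loc == "F5") report$f5 else report$f2
      ev <- rbind(ev, data.frame(
        locus = loc, size = NA_real_, height = bc$var_height,
        explanation = sprintf("het ratio %.2f below floor", bc$ratio_var_over_wt)))
    }
  }
  criteria <- unique(criteria)
  structure(list(sample_id = report$sample_id, detected = length(criteria) > 0,
                 criteria_hit = criteria, evidence = ev),
            class = "contamination_verdict")
}

#' Compare the STR identity of two sample reports
#'
#' Identity monitoring: two runs of the same DNA must show identical allele
#' sets at every co-called STR locus; a mismatch indicates a sample swap.
#' Loci uncalled in either sample are excluded and listed. With no co-called
#' locus the pair is incomparable (`match = NA`), which is distinct from a
#' mismatch.
#'
#' @param a,b `sample_report`s.
#' @return An `identity_comparison`: per-locus comparison data frame,
#'   `match` (TRUE/FALSE/NA) and `excluded_loci`.
#' @export
compare_identity <- function(a, b) {
  loci <- union(names(a$strs), names(b$strs))
  rows <- list(); excluded <- character()
  for (loc in loci) {
    ga <- if (!is.null(a$strs[[loc]])) a$strs[[loc]]$alleles else character()
    gb <- if (!is.null(b$strs[[loc]])) b$strs[[loc]]$alleles else character()
    if (!length(ga) || !length(gb)) { excluded <- c(excluded, loc); next }
    same <- identical(sort(ga), sort(gb))
    rows[[loc]] <- data.frame(locus = loc,
                              alleles_a = paste(sort(ga), collapse = "/"),
                              alleles_b = paste(sort(gb), collapse = "/"),
                              same = same)
  }
  cmp <- if (length(rows)) do.call(rbind, rows) else
    data.frame(locus = character(), alleles_a = character(),
               alleles_b = character(), same = logical())
  match <- if (!nrow(cmp)) NA else all(cmp$same)
  structure(list(sample_a = a$sample_id, sample_b = b$sample_id,
                 comparison = cmp, match = match, excluded_loci = excluded),
            class = "identity_comparison")
}

#' Read an STR allele-frequency table
#'
#' @param path CSV with columns `locus, allele, frequency`.
#' @return A `freq_table`: named list of named numeric frequency vectors,
#'   one per locus. Frequencies must lie in (0, 1] and sum to at most 1
#'   (plus rounding tolerance) per locus; partial tables are allowed.
#' @export
read_str_frequencies <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("locus", "allele", "frequency") %in% names(df)))
  if (any(df$frequency <= 0 | df$frequency > 1))
    stop("frequencies must lie in (0, 1]", call. = FALSE)
  out <- lapply(split(df, df$locus), function(d) {
    if (sum(d$frequency) > 1 + 1e-6)
      stop("frequencies at locus ", d$locus[1], " sum above 1", call. = FALSE)
    stats::setNames(d$frequency, as.character(d$allele))
  })
  structure(out, class = "freq_table")
}

#' The packaged demo STR frequency table
#'
#' A synthetic demonstration table with realistic European-like allele
#' frequencies for FGA and SE33. It is shipped for simulations and
#' random-match-probability examples only and is not a population reference.
#'
#' @return A `freq_table`.
#' @export
demo_str_frequencies <- function() {
  read_str_frequencies(system.file("extdata", "str_frequencies_demo.csv",
                                   package = "rflpmx"))
}

#' Random match probability of a multi-locus STR genotype
#'
#' Hardy-Weinberg product rule: per locus `p^2` for a homozygote or `2pq`
#' for a heterozygote, multiplied across loci. With the two highly
#' polymorphic loci of the default assay the most frequent genotype
#' combination lands in the 1e-3 to 1e-4 range.
#'
#' @param genotype Named list: locus -> character vector of the two allele
#'   labels (one label counts as homozygous).
#' @param freqs A `freq_table`.
#' @param min_freq Optional frequency floor for alleles absent from the
#'   table; without it a missing allele is an error.
#' @return Probability (numeric scalar).
#' @export
random_match_probability <- function(genotype, freqs, min_freq = NULL) {
  p <- 1
  for (loc in names(genotype)) {
    f <- freqs[[loc]]
    if (is.null(f)) stop("no frequencies for locus ", loc, call. = FALSE)
    al <- as.character(genotype[[loc]])
    if (length(al) == 1) al <- rep(al, 2)
    stopifnot(length(al) == 2)
    get_f <- function(a) {
      if (!is.na(f[a])) return(unname(f[a]))
      if (is.null(min_freq))
        stop("allele ", a, " absent from frequency table at locus ", loc,
             " (supply min_freq to floor unseen alleles)", call. = FALSE)
      min_freq
    }
    p1 <- get_f(al[1]); p2 <- get_f(al[2])
    p <- p * if (al[1] == al[2]) p1^2 else 2 * p1 * p2
  }
  p
}
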