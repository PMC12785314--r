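#' Genotype calling with digestion-control validation
#'
#' The assay's decision procedure. Each sample's peak table is interpreted
#' in four steps: (1) digestion-control validation — the uncut 289 bp F5
#' fragment must be absent (MnlI worked) and the uncut 339 bp FGA-intron
#' control must be absent while its 276 bp cut product is present (HindIII
#' worked); (2) biallelic calls for F5 (wt 92 / variant 129) and F2 (wt 246
#' / variant 226) gated on the relevant digestion control, with the
#' variant/wt peak-height ratio of heterozygotes checked against the 0.49
#' floor; (3) STR calls at FGA and SE33 with stutter classification (a peak
#' one repeat unit below a taller allele at up to 11% of its height) and
#' extra-peak accounting; (4) QC flags folded into a PASS / RETEST / FAIL
#' verdict.
#'
#' @name caller
NULL

#' Find the peak matching an expected fragment
#'
#' Returns the highest peak within `tol` bp of `size` on the given dye.
#' Height ties are broken by smaller absolute size deviation, then by
#' smaller size (deterministic).
#'
#' @param table A `peak_table`.
#' @param dye Channel colour.
#' @param size Expected apparent size (bp).
#' @param tol Matching tolerance (bp).
#' @return One-row data frame (dye, size, height), or `NULL` if no match.
#' @export
match_peak <- function(table, dye, size, tol) {
  stopifnot(tol > 0)
  pk <- table$peaks
  hit <- pk$dye == dye & abs(pk$size - size) <= tol
  if (!any(hit)) return(NULL)
  pk <- pk[hit, , drop = FALSE]
  ord <- order(-pk$height, abs(pk$size - size), pk$size)
  pk[ord[1], , drop = FALSE]
}

#' Validate the MnlI and HindIII digestion controls
#'
#' MnlI digestion is valid iff no peak at or above the calling threshold
#' sits at the uncut F5 position (289 bp, red). HindIII digestion is valid
#' iff the uncut control (339 bp, black) is absent AND the cut control
#' product (276 bp, black) is present at or above the calling threshold —
#' an empty channel proves nothing, so a missing cut control invalidates
#' the HindIII check.
#'
#' @param table A `peak_table`.
#' @param cfg An `assay_config`.
#' @return Named logical vector `c(mnl = ..., hind = ...)`.
#' @export
check_digestion <- function(table, cfg) {
  th <- cfg$thresholds
  tol <- th$size_match_tol
  present <- function(rule) {
    p <- match_peak(table, rule$dye, rule$size, tol)
    !is.null(p) && p$height >= th$allele_call_rfu
  }
  mnl <- !present(.frag(cfg, "F5", "uncut"))
  hind <- !present(.frag(cfg, "HIND_CTRL", "control_uncut")) &&
    present(.frag(cfg, "HIND_CTRL", "control_cut"))
  c(mnl = mnl, hind = hind)
}

#' Call the F5 or F2 biallelic genotype
#'
#' Presence of the wt and/or variant fragment above the calling threshold
#' determines the genotype; heterozygotes carry the variant/wt height
#' ratio. Calls must be gated on the locus's digestion control
#' (`digestion_ok = FALSE` forces `no_call`): an undigested sample would
#' otherwise masquerade as wild type, because the uncut F2 amplicon has the
#' same apparent size as the wt fragment.
#'
#' @param table A `peak_table`.
#' @param locus `"F5"` or `"F2"`.
#' @param cfg An `assay_config`.
#' @param digestion_ok Result of the relevant digestion control check.
#' @return A `biallelic_call`: locus, genotype (`wt/wt`, `var/wt`,
#'   `var/var`, `no_call`), wt/var heights, `ratio_var_over_wt` (defined for
#'   heterozygotes only), and `flags` (subset of `RATIO_LOW`, `LOW_SIGNAL`).
#' @export
call_biallelic <- function(table, locus, cfg, digestion_ok = TRUE) {
  th <- cfg$thresholds
  tol <- th$size_match_tol
  out <- list(locus = locus, genotype = "no_call",
              wt_height = NA_real_, var_height = NA_real_,
              ratio_var_over_wt = NA_real_, flags = character())
  class(out) <- "biallelic_call"
  if (!digestion_ok) return(out)
  get_h <- function(allele) {
    r <- .frag(cfg, locus, allele)
    p <- match_peak(table, r$dye, r$size, tol)
    if (is.null(p) || p$height < th$allele_call_rfu) NA_real_ else p$height
  }
  wt <- get_h("wt"); var <- get_h("variant")
  out$wt_height <- wt; out$var_height <- var
  ratio_min <- if (locus == "F5") th$het_ratio_min_f5 else th$het_ratio_min_f2
  if (!is.na(wt) && !is.na(var)) {
    out$genotype <- "var/wt"
    out$ratio_var_over_wt <- var / wt
    if (out$ratio_var_over_wt < ratio_min)
      out$flags <- paste0("RATIO_LOW_", locus)
  } else if (!is.na(wt)) {
    out$genotype <- "wt/wt"
  } else if (!is.na(var)) {
    out$genotype <- "var/var"
  } else {
    out$flags <- "LOW_SIGNAL"
  }
  out
}

#' Call an STR locus
#'
#' Candidate peaks are those at or above the calling threshold on the
#' locus's dye. In-range candidates are binned to the allele ladder and
#' classified tallest-first:
#' \itemize{
#'   \item a peak one repeat unit below an already-accepted taller allele at
#'     no more than `stutter_max_fraction` of its height is stutter;
#'   \item otherwise a peak at no less than `str_second_allele_min` of the
#'     tallest peak is an allele, up to the diploid expectation of two;
#'   \item everything else is an unexplained extra peak — the contamination
#'     signature. Extras at a stutter position record the offending
#'     fraction (a stutter-height exceedance).
#' }
#' A single accepted allele is reported homozygous (duplicated label).
#'
#' @param table A `peak_table`.
#' @param locus An `str_locus` (or locus id resolved against `cfg`).
#' @param cfg An `assay_config`.
#' @return An `str_call`: `alleles` (two labels, or empty), allele
#'   sizes/heights, `stutters` and `extras` data frames, `off_ladder`
#'   peaks, `low_signal` flag.
#' @export
call_str <- function(table, locus, cfg) {
  if (is.character(locus)) locus <- .str_locus(cfg, locus)
  th <- cfg$thresholds
  pk <- table$peaks[table$peaks$dye == locus$dye, , drop = FALSE]
  cand <- pk[pk$height >= th$allele_call_rfu, , drop = FALSE]
  empty_pk <- function() data.frame(size = numeric(), height = numeric(),
                                    parent_allele = character(),
                                    fraction = numeric())
  out <- list(locus = locus$locus, alleles = character(),
              allele_sizes = numeric(), allele_heights = numeric(),
              stutters = empty_pk(), extras = empty_pk(),
              off_ladder = cand[0, , drop = FALSE],
              low_signal = nrow(cand) == 0)
  class(out) <- "str_call"
  if (!nrow(cand)) return(out)

  binned <- lapply(cand$size, str_size_to_repeats, locus = locus,
                   tol = th$str_bin_tol)
  off <- vapply(binned, `[[`, TRUE, "off_ladder")
  out$off_ladder <- cand[off, , drop = FALSE]
  cand <- cand[!off, , drop = FALSE]
  if (!nrow(cand)) return(out)
  cand$allele <- vapply(binned[!off], `[[`, "", "label")
  cand <- cand[order(-cand$height, cand$size), , drop = FALSE]

  max_h <- cand$height[1]
  acc_allele <- integer()   # row indices of accepted alleles
  for (i in seq_len(nrow(cand))) {
    # stutter: one repeat below an accepted, strictly taller allele
    parent <- NA_integer_
    for (j in acc_allele) {
      if (abs((cand$size[j] - cand$size[i]) - locus$repeat_unit) <=
          th$str_bin_tol && cand$height[j] > cand$height[i]) {
        parent <- j; break
      }
    }
    frac <- if (!is.na(parent)) cand$height[i] / cand$height[parent] else NA_real_
    if (!is.na(parent) && frac <= th$stutter_max_fraction) {
      out$stutters <- rbind(out$stutters, data.frame(
        size = cand$size[i], height = cand$height[i],
        parent_allele = cand$allele[parent], fraction = frac))
    } else if (length(acc_allele) < 2 &&
               cand$height[i] >= th$str_second_allele_min * max_h) {
      acc_allele <- c(acc_allele, i)
    } else {
      out$extras <- rbind(out$extras, data.frame(
        size = cand$size[i], height = cand$height[i],
        parent_allele = if (is.na(parent)) NA_character_
                        else cand$allele[parent],
        fraction = frac))
    }
  }
  out$alleles <- cand$allele[acc_allele]
  out$allele_sizes <- cand$size[acc_allele]
  out$allele_heights <- cand$height[acc_allele]
  if (length(out$alleles) == 1) {      # single peak: homozygote
    out$alleles <- rep(out$alleles, 2)
    out$allele_sizes <- rep(out$allele_sizes, 2)
    out$allele_heights <- rep(out$allele_heights, 2)
  }
  # report alleles in ascending size order
  ord <- order(out$allele_sizes)
  out$alleles <- out$alleles[ord]
  out$allele_sizes <- out$allele_sizes[ord]
  out$allele_heights <- out$allele_heights[ord]
  out
}

#' Interpret one sample end to end
#'
#' Composes [check_digestion()], [call_biallelic()] and [call_str()], then
#' folds all QC observations into flags and a verdict: `FAIL` on any
#' digestion failure, `RETEST` on ratio/contamination flags, `PASS` when the
#' flag set is empty.
#'
#' @param table A `peak_table`.
#' @param cfg An `assay_config` (default: the packaged assay).
#' @return A `sample_report`.
#' @export
call_sample <- function(table, cfg = default_assay_config()) {
  dg <- check_digestion(table, cfg)
  f5 <- call_biallelic(table, "F5", cfg, digestion_ok = dg[["mnl"]])
  f2 <- call_biallelic(table, "F2", cfg, digestion_ok = dg[["hind"]])
  strs <- lapply(cfg$str_loci, function(l) call_str(table, l, cfg))
  names(strs) <- vapply(strs, `[[`, "", "locus")

  flags <- character()
  if (!dg[["mnl"]]) flags <- c(flags, "UNDIGESTED_MNL")
  if (!dg[["hind"]]) flags <- c(flags, "UNDIGESTED_HIND")
  flags <- c(flags, f5$flags, f2$flags)
  for (sc in strs) {
    if (nrow(sc$extras)) {
      stut_pos <- !is.na(sc$extras$parent_allele)
      if (any(stut_pos)) flags <- c(flags, "STUTTER_EXCESS")
      if (any(!stut_pos)) flags <- c(flags, "EXTRA_STR_ALLELE")
    }
    if (nrow(sc$off_ladder)) flags <- c(flags, "OFF_LADDER")
    if (sc$low_signal) flags <- c(flags, "LOW_SIGNAL")
  }
  flags <- unique(flags)
  verdict <- if (any(grepl("^UNDIGESTED", flags))) "FAIL"
             else if (length(flags)) "RETEST" else "PASS"
  structure(list(sample_id = table$sample_id, run_id = table$run_id,
                 f5 = f5, f2 = f2, strs = strs,
                 digestion_valid_mnl = dg[["mnl"]],
                 digestion_valid_hind = dg[["hind"]],
                 qc_flags = flags, verdict = verdict),
            class = "sample_report")
}

#' One-line genotype string for a report
#' @param report A `sample_report`.
#' @return Character like `"F5:var/wt F2:wt/wt FGA:21/24 SE33:17/28.2"`.
#' @export
genotype_string <- function(report) {
  strg <- vapply(report$strs, function(s)
    if (length(s$alleles)) paste(s$alleles, collapse = "/") else "no_call",
    character(1))
  paste0("F5:", report$f5$genotype, " F2:", report$f2$genotype, " ",
         paste(paste0(names(report$strs), ":", strg), collapse = " "))
}

#' Flatten sample reports to a data frame
#'
#' One row per sample with genotype strings, ratios, flags and verdict; the
#' shape written by the command-line `call` subcommand.
#'
#' @param reports List of `sample_report`s.
#' @return A data frame.
#' @export
reports_to_df <- function(reports) {
  do.call(rbind, lapply(reports, function(r) {
    strg <- vapply(r$strs, function(s)
      if (length(s$alleles)) paste(s$alleles, collapse = "/") else "",
      character(1))
    data.frame(sample = r$sample_id, run = r$run_id,
               f5 = r$f5$genotype, f2 = r$f2$genotype,
               fga = strg[["FGA"]], se33 = strg[["SE33"]],
               ratio_f5 = round(r$f5$ratio_var_over_wt, 3),
               ratio_f2 = round(r$f2$ratio_var_over_wt, 3),
               flags = paste(r$qc_flags, collapse = ";"),
               verdict = r$verdict, stringsAsFactors = FALSE)
  }))
}

#' @export
print.sample_report <- function(x, ...) {
  cat(sprintf("Sample %s (%s): %s\n", x$sample_id, x$run_id,
              genotype_string(x)))
  cat(sprintf("  digestion: MnlI %s, HindIII %s\n",
              if (x$digestion_valid_mnl) "ok" else "FAILED",
              if (x$digestion_valid_hind) "ok" else "FAILED"))
  if (!is.na(x$f5$ratio_var_over_wt))
    cat(sprintf("  F5 het ratio %.2f\n", x$f5$ratio_var_over_wt))
  if (!is.na(x$f2$ratio_var_over_wt))
    cat(sprintf("  F2 het ratio %.2f\n", x$f2$ratio_var_over_wt))
  cat(sprintf("  flags: %s\n  verdict: %s\n",
              if (length(x$qc_flags)) paste(x$qc_flags, collapse = ", ")
              else "none", x$verdict))
  invisible(x)
}
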