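#' Validation statistics
#'
#' The assay's interpretation thresholds are derived from empirical moments
#' (mean +/- k SD of heterozygous peak-height ratios and stutter fractions),
#' and its validation studies are summarised as proportions with Wilson
#' score confidence intervals.
#'
#' @name valstats
NULL

#' Derive a threshold from a mean and standard deviation
#'
#' `mean + k * sd`, with the rounding the assay's printed cut-offs use:
#' ratios to 2 decimals (0.61 - 2 x 0.06 = 0.49), stutter percentages to the
#' nearest integer percent (7.6 + 2 x 1.8 = 11.2 -> 11).
#'
#' @param mean,sd Moments, in the same units (fraction or percent).
#' @param k Signed SD multiplier (e.g. -2 for a lower cut, +2 for an upper).
#' @param round_to `"ratio"` (2 decimals), `"percent"` (integer) or
#'   `"none"`.
#' @return Threshold in the input units.
#' @export
threshold_from_moments <- function(mean, sd, k, round_to = c("ratio", "percent", "none")) {
  stopifnot(sd >= 0)
  round_to <- match.arg(round_to)
  x <- mean + k * sd
  switch(round_to,
         ratio = round(x, 2),
         percent = round(x),
         none = x)
}

#' Wilson score confidence interval for a proportion
#'
#' At `successes = trials` the lower bound has the closed form
#' `n / (n + z^2)`; for the 30/30 detection rates of the mixture study this
#' gives 0.8865, printing as 0.89.
#'
#' @param successes,trials Non-negative counts, `successes <= trials`.
#' @param confidence Confidence level (default 0.95).
#' @return A `proportion_ci`: successes, trials, point, lower, upper,
#'   method.
#' @export
wilson_ci <- function(successes, trials, confidence = 0.95) {
  if (trials < 1 || successes < 0 || successes > trials)
    stop("invalid counts: need 0 <= successes <= trials, trials >= 1",
         call. = FALSE)
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  phat <- successes / trials
  denom <- 1 + z^2 / trials
  centre <- (phat + z^2 / (2 * trials)) / denom
  half <- (z / denom) * sqrt(phat * (1 - phat) / trials +
                             z^2 / (4 * trials^2))
  structure(list(successes = successes, trials = trials, point = phat,
                 lower = max(0, centre - half), upper = min(1, centre + half),
                 confidence = confidence, method = "wilson"),
            class = "proportion_ci")
}

#' @export
print.proportion_ci <- function(x, ...) {
  cat(sprintf("%d/%d = %.3f, %d%% CI [%.2f-%.2f] (Wilson)\n", x$successes,
              x$trials, x$point, round(100 * x$confidence), x$lower, x$upper))
  invisible(x)
}

.gt_str <- function(g) paste0("F5:", g$f5, " F2:", g$f2)

#' Concordance of called genotypes against truth
#'
#' Per-genotype-category and overall concordance of the F5/F2 calls against
#' ground truth, with Wilson CIs, plus sensitivity and specificity under the
#' both-locus concordance definition: a carrier (any non-wild-type truth at
#' F5 or F2) counts as a true positive only when both loci were called
#' concordantly.
#'
#' @param truth List of `sample_genotype` objects (ground truth).
#' @param reports List of `sample_report`s, same length and order.
#' @param confidence CI level.
#' @return A `concordance_summary`: `by_category` data frame, `overall`,
#'   `sensitivity`, `specificity` (each a `proportion_ci`).
#' @export
concordance_summary <- function(truth, reports, confidence = 0.95) {
  if (length(truth) != length(reports))
    stop("truth and reports must have equal length", call. = FALSE)
  ok <- vapply(seq_along(truth), function(i)
    identical(truth[[i]]$f5, reports[[i]]$f5$genotype) &&
    identical(truth[[i]]$f2, reports[[i]]$f2$genotype), logical(1))
  cat_lab <- vapply(truth, .gt_str, character(1))
  by_cat <- do.call(rbind, lapply(unique(cat_lab), function(lab) {
    idx <- cat_lab == lab
    ci <- wilson_ci(sum(ok[idx]), sum(idx), confidence)
    data.frame(category = lab, n = sum(idx), concordant = sum(ok[idx]),
               fraction = ci$point, lower = ci$lower, upper = ci$upper)
  }))
  carrier <- vapply(truth, function(g) g$f5 != "wt/wt" || g$f2 != "wt/wt",
                    logical(1))
  sens <- if (any(carrier)) wilson_ci(sum(ok[carrier]), sum(carrier),
                                      confidence) else NULL
  spec <- if (any(!carrier)) wilson_ci(sum(ok[!carrier]), sum(!carrier),
                                       confidence) else NULL
  structure(list(by_category = by_cat,
                 overall = wilson_ci(sum(ok), length(ok), confidence),
                 sensitivity = sens, specificity = spec),
            class = "concordance_summary")
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat("Concordance by genotype category:\n")
  print(x$by_category, row.names = FALSE)
  cat("Overall: "); print(x$overall)
  if (!is.null(x$sensitivity)) { cat("Sensitivity: "); print(x$sensitivity) }
  if (!is.null(x$specificity)) { cat("Specificity: "); print(x$specificity) }
  invisible(x)
}
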