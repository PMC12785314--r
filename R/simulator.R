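#' Synthetic peak-table simulator
#'
#' Generates electropherogram peak tables with the assay's statistical
#' structure so that every validation experiment can be re-run in silico:
#' per-allele peak heights (log-normal base, saturation-clipped at 32000
#' RFU), heterozygous variant/wt height ratios N(0.61, 0.06^2) for F5 and
#' N(0.67, 0.09^2) for F2, stutter peaks one repeat unit below each STR
#' allele at N(7.6%, 1.8^2 %) (FGA) and N(7.6%, 1.6^2 %) (SE33) of the
#' parent height, background noise below 50 RFU, digestion-failure modes
#' that resurrect the uncut 289/339 bp fragments, and two-person DNA
#' mixtures at a configurable ng:ng ratio with linear height scaling.
#'
#' All draws go through R's global RNG: set a seed (or use the `seed`
#' arguments of the study drivers) for byte-identical output.
#'
#' @name simulator
NULL

#' Simulator parameters
#'
#' Defaults are the assay's measured operating conditions; heights use a
#' log-normal with median 8000 RFU, placing single-allele peaks well inside
#' the instrument's 250-32000 RFU working range.
#'
#' @param het_ratio_f5,het_ratio_f2 `c(mean, sd)` of the heterozygous
#'   variant/wt height ratio (truncated to (0, 1.5)).
#' @param stutter_fga,stutter_se33 `c(mean, sd)` of the stutter height
#'   fraction (truncated at 0).
#' @param base_height_meanlog,base_height_sdlog Log-normal parameters of the
#'   per-locus allele unit height.
#' @param noise_rate Poisson mean of the background noise peak count.
#' @param noise_max Upper bound of the uniform noise height (RFU).
#' @param saturation Clipping ceiling (RFU).
#' @return A `sim_params` list.
#' @export
sim_params <- function(het_ratio_f5 = c(mean = 0.61, sd = 0.06),
                       het_ratio_f2 = c(mean = 0.67, sd = 0.09),
                       stutter_fga = c(mean = 0.076, sd = 0.018),
                       stutter_se33 = c(mean = 0.076, sd = 0.016),
                       base_height_meanlog = log(8000),
                       base_height_sdlog = 0.3,
                       noise_rate = 3, noise_max = 50,
                       saturation = 32000) {
  p <- list(het_ratio_f5 = het_ratio_f5, het_ratio_f2 = het_ratio_f2,
            stutter_fga = stutter_fga, stutter_se33 = stutter_se33,
            base_height_meanlog = base_height_meanlog,
            base_height_sdlog = base_height_sdlog,
            noise_rate = noise_rate, noise_max = noise_max,
            saturation = saturation)
  for (nm in c("het_ratio_f5", "het_ratio_f2", "stutter_fga", "stutter_se33")) {
    stopifnot(p[[nm]][["sd"]] >= 0, p[[nm]][["mean"]] > 0,
              p[[nm]][["mean"]] < 1)
  }
  structure(p, class = "sim_params")
}

#' A ground-truth sample genotype
#'
#' @param f5,f2 One of `"wt/wt"`, `"var/wt"`, `"var/var"`.
#' @param fga,se33 Character vectors of two allele labels on the ladder.
#' @return A `sample_genotype`.
#' @export
sample_genotype_fixed <- function(f5 = "wt/wt", f2 = "wt/wt",
                                  fga = c("21", "24"),
                                  se33 = c("17", "28.2")) {
  f5 <- match.arg(f5, c("wt/wt", "var/wt", "var/var"))
  f2 <- match.arg(f2, c("wt/wt", "var/wt", "var/var"))
  structure(list(f5 = f5, f2 = f2, fga = as.character(fga),
                 se33 = as.character(se33)), class = "sample_genotype")
}

#' Draw a random genotype
#'
#' STR alleles are i.i.d. draws from the frequency table (Hardy-Weinberg);
#' F5/F2 states are fixed by argument or drawn from carrier frequencies.
#'
#' @param freqs A `freq_table` covering FGA and SE33.
#' @param f5,f2 Fixed variant states, or `NULL` to draw.
#' @param carrier_freq Named vector of heterozygous-carrier probabilities
#'   used when a state is drawn (homozygous carriers are not drawn; fix the
#'   state explicitly to simulate them).
#' @return A `sample_genotype`.
#' @export
sample_genotype <- function(freqs, f5 = NULL, f2 = NULL,
                            carrier_freq = c(f5 = 0.05, f2 = 0.02)) {
  if (!length(freqs)) stop("empty frequency table", call. = FALSE)
  draw_locus <- function(loc) {
    f <- freqs[[loc]]
    if (is.null(f)) stop("no frequencies for locus ", loc, call. = FALSE)
    sample(names(f), 2, replace = TRUE, prob = f)
  }
  draw_state <- function(p_het)
    if (stats::runif(1) < p_het) "var/wt" else "wt/wt"
  sample_genotype_fixed(
    f5 = if (is.null(f5)) draw_state(carrier_freq[["f5"]]) else f5,
    f2 = if (is.null(f2)) draw_state(carrier_freq[["f2"]]) else f2,
    fga = draw_locus("FGA"), se33 = draw_locus("SE33"))
}

#' Simulator instruction for one sample
#'
#' @param primary A `sample_genotype`.
#' @param contaminant A second `sample_genotype`, or `NULL`.
#' @param ratio Contaminant:primary amount ratio in ng:ng (e.g. `1/20`);
#'   must be positive when a contaminant is present.
#' @param digestion_failure `"none"`, `"mnl"`, `"hind"` or `"both"`.
#' @return A `mixture_spec`.
#' @export
mixture_spec <- function(primary, contaminant = NULL, ratio = 0,
                         digestion_failure = c("none", "mnl", "hind", "both")) {
  digestion_failure <- match.arg(digestion_failure)
  if (!is.null(contaminant) && ratio <= 0)
    stop("mixture ratio must be positive when a contaminant is present",
         call. = FALSE)
  structure(list(primary = primary, contaminant = contaminant, ratio = ratio,
                 digestion_failure = digestion_failure),
            class = "mixture_spec")
}

.rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x <= lo | x >= hi))
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

# contribute peaks of one genotype at a height scale; returns rows
.genotype_peaks <- function(gt, scale, params, cfg, fail_mnl, fail_hind) {
  rows <- list()
  add <- function(dye, size, height)
    rows[[length(rows) + 1]] <<- data.frame(dye = dye, size = size,
                                            height = height)
  base <- function() scale * stats::rlnorm(1, params$base_height_meanlog,
                                           params$base_height_sdlog)
  # --- F5 (MnlI digest) ------------------------------------------------
  h5 <- base()
  if (fail_mnl) {
    r <- .frag(cfg, "F5", "uncut")
    add(r$dye, r$size, 2 * h5)
  } else {
    wt <- .frag(cfg, "F5", "wt"); vr <- .frag(cfg, "F5", "variant")
    switch(gt$f5,
           "wt/wt" = add(wt$dye, wt$size, 2 * h5),
           "var/wt" = {
             add(wt$dye, wt$size, h5)
             rr <- .rnorm_trunc(1, params$het_ratio_f5[["mean"]],
                                params$het_ratio_f5[["sd"]], 0, 1.5)
             add(vr$dye, vr$size, h5 * rr)
           },
           "var/var" = add(vr$dye, vr$size, 2 * h5))
  }
  # --- F2 (HindIII digest; uncut amplicon sizes like the wt fragment) --
  h2 <- base()
  wt <- .frag(cfg, "F2", "wt"); vr <- .frag(cfg, "F2", "variant")
  if (fail_hind) {
    add(wt$dye, wt$size, 2 * h2)
  } else {
    switch(gt$f2,
           "wt/wt" = add(wt$dye, wt$size, 2 * h2),
           "var/wt" = {
             add(wt$dye, wt$size, h2)
             rr <- .rnorm_trunc(1, params$het_ratio_f2[["mean"]],
                                params$het_ratio_f2[["sd"]], 0, 1.5)
             add(vr$dye, vr$size, h2 * rr)
           },
           "var/var" = add(vr$dye, vr$size, 2 * h2))
  }
  # --- HindIII digestion control --------------------------------------
  hc <- base()
  ctrl <- if (fail_hind) .frag(cfg, "HIND_CTRL", "control_uncut")
          else .frag(cfg, "HIND_CTRL", "control_cut")
  add(ctrl$dye, ctrl$size, 2 * hc)
  # --- STR loci with stutter ------------------------------------------
  str_gt <- list(FGA = gt$fga, SE33 = gt$se33)
  stut_par <- list(FGA = params$stutter_fga, SE33 = params$stutter_se33)
  for (loc_id in names(str_gt)) {
    locus <- .str_locus(cfg, loc_id)
    hs <- base()
    for (al in str_gt[[loc_id]]) {
      sz <- str_repeats_to_size(locus, al)
      add(locus$dye, sz, hs)
      frac <- .rnorm_trunc(1, stut_par[[loc_id]][["mean"]],
                           stut_par[[loc_id]][["sd"]], lo = 0)
      st_h <- hs * frac
      if (st_h >= 1 && sz - locus$repeat_unit > 0)
        add(locus$dye, sz - locus$repeat_unit, st_h)
    }
  }
  do.call(rbind, rows)
}

#' Synthesize one peak table
#'
#' Builds every allele's peak at its configured apparent size on the
#' correct dye, scales contaminant peaks linearly by the ng:ng ratio, sums
#' coincident sizes, adds stutter and background noise, clips at
#' saturation, and applies the requested digestion-failure mode (uncut
#' 289/339 bp peaks replacing the digested products).
#'
#' @param spec A `mixture_spec`.
#' @param params A `sim_params`.
#' @param cfg An `assay_config`.
#' @param sample_id,run_id Identifiers for the output table.
#' @param noise Emit background noise peaks (default `TRUE`).
#' @return A `peak_table`.
#' @export
synthesize <- function(spec, params = sim_params(),
                       cfg = default_assay_config(),
                       sample_id = "sim1", run_id = "simrun", noise = TRUE) {
  fail_mnl <- spec$digestion_failure %in% c("mnl", "both")
  fail_hind <- spec$digestion_failure %in% c("hind", "both")
  peaks <- .genotype_peaks(spec$primary, 1, params, cfg, fail_mnl, fail_hind)
  if (!is.null(spec$contaminant))
    peaks <- rbind(peaks,
                   .genotype_peaks(spec$contaminant, spec$ratio, params, cfg,
                                   fail_mnl, fail_hind))
  if (noise) {
    k <- stats::rpois(1, params$noise_rate)
    if (k > 0)
      peaks <- rbind(peaks, data.frame(
        dye = sample(c("blue", "green", "black", "red"), k, replace = TRUE),
        size = stats::runif(k, 60, 450),
        height = stats::runif(k, 1, params$noise_max - 1)))
  }
  # merge coincident sizes (same dye, same bp position)
  key <- paste(peaks$dye, round(peaks$size, 1))
  merged <- do.call(rbind, lapply(split(peaks, key), function(d)
    data.frame(dye = d$dye[1], size = d$size[1], height = sum(d$height))))
  merged$height <- pmin(merged$height, params$saturation)
  merged <- merged[merged$height >= 1, , drop = FALSE]
  peak_table(sample_id, run_id, merged, saturation_rfu = params$saturation)
}

# Table-2 cohort composition: 31 double-wt, 16 F5 het, 14 F2 het, 1 F5 hom
.concordance_composition <- function() {
  c(rep("wt_wt", 31), rep("f5het_wt", 16), rep("wt_f2het", 14), "f5hom_wt")
}

.state_pair <- function(code) {
  switch(code,
         wt_wt = c("wt/wt", "wt/wt"),
         f5het_wt = c("var/wt", "wt/wt"),
         wt_f2het = c("wt/wt", "var/wt"),
         f5hom_wt = c("var/var", "wt/wt"))
}

# Table-4 mixture layout: (primary, contaminant) pair counts summing to 30
.mixture_composition <- function() {
  data.frame(
    primary = c("wt_wt", "f5het_wt", "wt_f2het", "wt_wt", "wt_wt"),
    contaminant = c("wt_wt", "wt_wt", "wt_wt", "f5het_wt", "wt_f2het"),
    n = c(11, 7, 2, 5, 5))
}

#' Run an in-silico validation study
#'
#' Re-runs one of the assay's validation experiments on synthetic data:
#' \describe{
#'   \item{`concordance`}{Simulates the 62-sample concordance cohort (31
#'     double wild-type, 16 F5 heterozygotes, 14 F2 heterozygotes, 1 F5
#'     homozygote), calls every sample, and tabulates per-category and
#'     overall concordance with Wilson CIs.}
#'   \item{`mixture_1to10`, `mixture_1to20`}{Simulates 30 two-person
#'     mixtures at the named ng:ng ratio with the validation study's
#'     variant-state layout and random STR genotypes, and tabulates
#'     detection by the three contamination criteria.}
#'   \item{`ratio_stats`, `stutter_stats`}{Simulates `n` heterozygous (or
#'     plain) samples and reports the empirical mean and SD of the called
#'     het ratios, or of the called stutter fractions.}
#' }
#'
#' @param study Study name (see above).
#' @param params A `sim_params`.
#' @param cfg An `assay_config`.
#' @param freqs A `freq_table` for random STR genotypes.
#' @param n Sample count (defaults: 62 for concordance, 30 for mixtures,
#'   1000 for moment studies).
#' @param seed Integer seed (applied via `set.seed`).
#' @return A `validation_study` result list; shape depends on the study.
#' @export
run_validation_study <- function(study = c("concordance", "mixture_1to10",
                                           "mixture_1to20", "ratio_stats",
                                           "stutter_stats"),
                                 params = sim_params(),
                                 cfg = default_assay_config(),
                                 freqs = demo_str_frequencies(),
                                 n = NULL, seed = 1L) {
  study <- match.arg(study)
  set.seed(seed)
  out <- switch(study,
    concordance = {
      codes <- .concordance_composition()
      if (!is.null(n)) codes <- rep_len(codes, n)
      truth <- list(); reports <- list()
      for (i in seq_along(codes)) {
        st <- .state_pair(codes[i])
        gt <- sample_genotype(freqs, f5 = st[1], f2 = st[2])
        truth[[i]] <- gt
        tb <- synthesize(mixture_spec(gt), params, cfg,
                         sample_id = sprintf("conc%02d", i))
        reports[[i]] <- call_sample(tb, cfg)
      }
      summ <- concordance_summary(truth, reports)
      list(summary = summ, truth = truth, reports = reports,
           n = length(codes),
           percent_concordant = 100 * summ$overall$point)
    },
    mixture_1to10 = .mixture_study(1 / 10, params, cfg, freqs, n),
    mixture_1to20 = .mixture_study(1 / 20, params, cfg, freqs, n),
    ratio_stats = {
      if (is.null(n)) n <- 1000
      r5 <- r2 <- numeric(n)
      for (i in seq_len(n)) {
        gt <- sample_genotype(freqs, f5 = "var/wt", f2 = "var/wt")
        tb <- synthesize(mixture_spec(gt), params, cfg,
                         sample_id = sprintf("rat%04d", i))
        rep_i <- call_sample(tb, cfg)
        r5[i] <- rep_i$f5$ratio_var_over_wt
        r2[i] <- rep_i$f2$ratio_var_over_wt
      }
      list(n = n,
           f5 = c(mean = mean(r5, na.rm = TRUE), sd = stats::sd(r5, na.rm = TRUE)),
           f2 = c(mean = mean(r2, na.rm = TRUE), sd = stats::sd(r2, na.rm = TRUE)))
    },
    stutter_stats = {
      if (is.null(n)) n <- 1000
      fga <- c(); se33 <- c()
      for (i in seq_len(n)) {
        gt <- sample_genotype(freqs)
        tb <- synthesize(mixture_spec(gt), params, cfg,
                         sample_id = sprintf("stut%04d", i))
        rep_i <- call_sample(tb, cfg)
        fga <- c(fga, rep_i$strs$FGA$stutters$fraction)
        se33 <- c(se33, rep_i$strs$SE33$stutters$fraction)
      }
      list(n = n,
           fga = c(mean = mean(fga), sd = stats::sd(fga)),
           se33 = c(mean = mean(se33), sd = stats::sd(se33)))
    })
  structure(c(list(study = study, seed = seed), out),
            class = "validation_study")
}

.mixture_study <- function(ratio, params, cfg, freqs, n = NULL) {
  comp <- .mixture_composition()
  pairs <- comp[rep(seq_len(nrow(comp)), comp$n), c("primary", "contaminant")]
  if (!is.null(n)) pairs <- pairs[rep_len(seq_len(nrow(pairs)), n), ]
  detected <- logical(nrow(pairs)); criteria <- character(0)
  verdicts <- list()
  for (i in seq_len(nrow(pairs))) {
    sp <- .state_pair(pairs$primary[i]); sc <- .state_pair(pairs$contaminant[i])
    prim <- sample_genotype(freqs, f5 = sp[1], f2 = sp[2])
    cont <- sample_genotype(freqs, f5 = sc[1], f2 = sc[2])
    tb <- synthesize(mixture_spec(prim, cont, ratio), params, cfg,
                     sample_id = sprintf("mix%02d", i))
    v <- assess_contamination(call_sample(tb, cfg), cfg)
    detected[i] <- v$detected
    criteria <- c(criteria, v$criteria_hit)
    verdicts[[i]] <- v
  }
  ci <- wilson_ci(sum(detected), length(detected))
  list(ratio = ratio, n = length(detected), detected = sum(detected),
       percent_detected = 100 * mean(detected),
       ci = ci, criteria_counts = table(criteria), verdicts = verdicts)
}

#' @export
print.validation_study <- function(x, ...) {
  cat("In-silico validation study:", x$study, "(seed", x$seed, ")\n")
  if (x$study == "concordance") {
    cat(sprintf("  %d samples, %.1f%% concordant\n", x$n,
                x$percent_concordant))
    print(x$summary)
  } else if (grepl("^mixture", x$study)) {
    cat(sprintf("  1:%d mixtures: %d/%d detected (%.1f%%), CI [%.2f-%.2f]\n",
                round(1 / x$ratio), x$detected, x$n, x$percent_detected,
                x$ci$lower, x$ci$upper))
    print(x$criteria_counts)
  } else {
    for (nm in intersect(c("f5", "f2", "fga", "se33"), names(x)))
      cat(sprintf("  %s: mean %.4f, sd %.4f (n = %d)\n", nm,
                  x[[nm]][["mean"]], x[[nm]][["sd"]], x$n))
  }
  invisible(x)
}
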