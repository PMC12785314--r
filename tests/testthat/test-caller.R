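cfg <- default_assay_config()

test_that("match_peak picks the highest in-window peak with deterministic ties", {
  tb <- make_table(red = c("92.3" = 5000))
  expect_equal(match_peak(tb, "red", 92, 1)$size, 92.3)
  tb2 <- make_table(red = c("94.0" = 5000))
  expect_null(match_peak(tb2, "red", 92, 1))
  # height tie: smaller |delta size| wins
  tb3 <- make_table(red = c("91.5" = 5000, "92.4" = 5000))
  expect_equal(match_peak(tb3, "red", 92, 1)$size, 92.4)
  # full tie on height and |delta|: deterministic pick of the smaller size
  tb4 <- make_table(red = c("91.6" = 5000, "92.4" = 5000))
  expect_equal(match_peak(tb4, "red", 92, 1)$size, 91.6)
  # taller peak beats closer peak
  tb5 <- make_table(red = c("92.0" = 1000, "92.8" = 4000))
  expect_equal(match_peak(tb5, "red", 92, 1)$size, 92.8)
})

test_that("digestion controls: uncut 289/339 peaks and the 276 cut control", {
  # undigested sample: both uncut fragments present
  und <- make_table(red = c("289" = 8000, "92" = 300),
                    black = c("339" = 9000))
  expect_equal(unname(check_digestion(und, cfg)), c(FALSE, FALSE))
  # clean digest: 276 present, 289/339 absent
  ok <- make_table(red = c("92" = 9000), black = c("276" = 7000))
  expect_equal(unname(check_digestion(ok, cfg)), c(TRUE, TRUE))
  # empty table: no uncut peak, but no cut control either
  empty <- peak_table("e")
  expect_equal(unname(check_digestion(empty, cfg)), c(TRUE, FALSE))
  # sub-threshold residual uncut peak does not fail the control
  faint <- make_table(red = c("289" = 120, "92" = 9000),
                      black = c("276" = 7000))
  expect_equal(unname(check_digestion(faint, cfg)), c(TRUE, TRUE))
})

test_that("biallelic genotypes follow fragment presence and the ratio rule", {
  wt <- call_biallelic(make_table(red = c("92" = 9000)), "F5", cfg)
  expect_equal(wt$genotype, "wt/wt")
  expect_true(is.na(wt$ratio_var_over_wt))
  het <- call_biallelic(make_table(red = c("92" = 9000, "129" = 5490)),
                        "F5", cfg)
  expect_equal(het$genotype, "var/wt")
  expect_equal(het$ratio_var_over_wt, 0.61)
  expect_length(het$flags, 0)
  # 4000/9000 = 0.444 below the 0.49 floor -> re-test flag
  low <- call_biallelic(make_table(red = c("92" = 9000, "129" = 4000)),
                        "F5", cfg)
  expect_equal(low$genotype, "var/wt")
  expect_lt(low$ratio_var_over_wt, 0.49)
  expect_equal(low$flags, "RATIO_LOW_F5")
  hom <- call_biallelic(make_table(red = c("129" = 9000)), "F5", cfg)
  expect_equal(hom$genotype, "var/var")
  none <- call_biallelic(make_table(red = c("92" = 40)), "F5", cfg)
  expect_equal(none$genotype, "no_call")
  expect_equal(none$flags, "LOW_SIGNAL")
  # gating: a failed digest forces no_call regardless of peaks
  gated <- call_biallelic(make_table(red = c("92" = 9000)), "F5", cfg,
                          digestion_ok = FALSE)
  expect_equal(gated$genotype, "no_call")
})

test_that("F2 calls use the 226/246 pair with its own ratio flag", {
  het <- call_biallelic(make_table(red = c("246" = 9000, "226" = 6030)),
                        "F2", cfg)
  expect_equal(het$genotype, "var/wt")
  expect_equal(het$ratio_var_over_wt, 0.67)
  low <- call_biallelic(make_table(red = c("246" = 9000, "226" = 4000)),
                        "F2", cfg)
  expect_equal(low$flags, "RATIO_LOW_F2")
})

test_that("STR calls classify alleles, stutter and extras", {
  fga <- cfg$str_loci[[1]]
  sizes <- .str_sizes(cfg, "FGA", c("21", "23"))
  # two alleles two repeats apart, each with 7% stutter one repeat below
  tb <- make_table(green = stats::setNames(
    c(8000, 8000, 560, 560), c(sizes, sizes - 4)))
  call <- call_str(tb, fga, cfg)
  expect_equal(call$alleles, c("21", "23"))
  expect_equal(nrow(call$stutters), 2)
  expect_equal(call$stutters$fraction, c(0.07, 0.07))
  expect_equal(nrow(call$extras), 0)
  # 15% stutter-position peak exceeds the 11% ceiling -> extra, not stutter
  tb2 <- make_table(green = stats::setNames(c(8000, 1200),
                                            c(sizes[1], sizes[1] - 4)))
  call2 <- call_str(tb2, fga, cfg)
  expect_equal(call2$alleles, c("21", "21"))  # single peak = homozygote
  expect_equal(nrow(call2$stutters), 0)
  expect_equal(nrow(call2$extras), 1)
  expect_equal(call2$extras$parent_allele, "21")
  expect_equal(call2$extras$fraction, 0.15)
  # three allele-height peaks: diploid expectation keeps two, third is extra
  s3 <- .str_sizes(cfg, "FGA", c("19", "22", "25"))
  tb3 <- make_table(green = stats::setNames(c(8000, 7900, 7800), s3))
  call3 <- call_str(tb3, fga, cfg)
  expect_length(call3$alleles, 2)
  expect_equal(nrow(call3$extras), 1)
  # low contaminant-height peak off any stutter position -> extra
  tb4 <- make_table(green = stats::setNames(c(8000, 400),
                                            .str_sizes(cfg, "FGA",
                                                       c("21", "25"))))
  call4 <- call_str(tb4, fga, cfg)
  expect_equal(call4$alleles, c("21", "21"))
  expect_equal(nrow(call4$extras), 1)
  expect_true(is.na(call4$extras$parent_allele))
})

test_that("adjacent-repeat heterozygotes are not mistaken for stutter", {
  fga <- cfg$str_loci[[1]]
  sizes <- .str_sizes(cfg, "FGA", c("21", "22"))
  tb <- make_table(green = stats::setNames(c(8600, 8000), sizes))
  call <- call_str(tb, fga, cfg)
  expect_setequal(call$alleles, c("21", "22"))
  expect_equal(nrow(call$stutters), 0)
})

test_that("off-ladder peaks are flagged, not crashed on", {
  fga <- cfg$str_loci[[1]]
  tb <- make_table(green = c("60" = 5000))
  call <- call_str(tb, fga, cfg)
  expect_equal(nrow(call$off_ladder), 1)
  expect_length(call$alleles, 0)
})

test_that("call_sample composes calls, flags and verdicts", {
  # clean double heterozygote -> PASS
  rep1 <- call_sample(hand_table("var/wt", "var/wt"), cfg)
  expect_equal(rep1$f5$genotype, "var/wt")
  expect_equal(rep1$f2$genotype, "var/wt")
  expect_equal(rep1$strs$FGA$alleles, c("21", "24"))
  expect_equal(rep1$strs$SE33$alleles, c("17", "28.2"))
  expect_equal(rep1$verdict, "PASS")
  expect_length(rep1$qc_flags, 0)
  # undigested sample -> both loci no_call, verdict FAIL
  und <- make_table(red = c("289" = 8000, "246" = 9000),
                    black = c("339" = 9000),
                    green = c("120" = 8000), blue = c("329" = 8000))
  rep2 <- call_sample(und, cfg)
  expect_equal(rep2$f5$genotype, "no_call")
  expect_equal(rep2$f2$genotype, "no_call")
  expect_true(all(c("UNDIGESTED_MNL", "UNDIGESTED_HIND") %in% rep2$qc_flags))
  expect_equal(rep2$verdict, "FAIL")
  # low het ratio -> RETEST
  low <- hand_table("var/wt", "wt/wt")
  low$peaks$height[low$peaks$size == 129] <- 3000L
  rep3 <- call_sample(low, cfg)
  expect_equal(rep3$verdict, "RETEST")
  expect_true("RATIO_LOW_F5" %in% rep3$qc_flags)
})

test_that("calls are invariant under height rescaling below saturation", {
  tb <- hand_table("var/wt", "wt/wt", h = 4000)
  tb2 <- tb
  tb2$peaks$height <- tb2$peaks$height * 3L
  r1 <- call_sample(tb, cfg); r2 <- call_sample(tb2, cfg)
  expect_equal(r1$f5$genotype, r2$f5$genotype)
  expect_equal(r1$f5$ratio_var_over_wt, r2$f5$ratio_var_over_wt)
  expect_equal(r1$strs$FGA$alleles, r2$strs$FGA$alleles)
  expect_equal(r1$qc_flags, r2$qc_flags)
  expect_equal(r1$verdict, r2$verdict)
})

test_that("raising the calling threshold never adds alleles", {
  set.seed(31)
  freqs <- demo_str_frequencies()
  for (i in 1:10) {
    gt <- sample_genotype(freqs)
    tb <- synthesize(mixture_spec(gt), cfg = cfg)
    lo <- call_sample(tb, cfg)
    hi_cfg <- cfg
    hi_cfg$thresholds$allele_call_rfu <- 400
    hi <- call_sample(tb, hi_cfg)
    for (loc in c("FGA", "SE33"))
      expect_true(all(hi$strs[[loc]]$alleles %in% lo$strs[[loc]]$alleles))
  }
})
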