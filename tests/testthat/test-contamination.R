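cfg <- default_assay_config()

test_that("clean single-source reports trigger no criterion", {
  rep <- call_sample(hand_table("var/wt", "wt/wt"), cfg)
  v <- assess_contamination(rep, cfg)
  expect_false(v$detected)
  expect_length(v$criteria_hit, 0)
  expect_equal(nrow(v$evidence), 0)
})

test_that("an extra STR peak raises EXTRA_ALLELE with evidence", {
  tb <- hand_table("wt/wt", "wt/wt")
  extra_size <- .str_sizes(cfg, "SE33", "20")
  tb$peaks <- rbind(tb$peaks,
                    data.frame(dye = "blue", size = extra_size, height = 600L))
  tb <- peak_table(tb$sample_id, tb$run_id, tb$peaks)
  v <- assess_contamination(call_sample(tb, cfg), cfg)
  expect_true(v$detected)
  expect_equal(v$criteria_hit, "EXTRA_ALLELE")
  expect_equal(v$evidence$locus, "SE33")
  expect_equal(v$evidence$height, 600)
})

test_that("a contaminant allele on a stutter position raises STUTTER_EXCESS", {
  # stutter position of the FGA 24 allele carries 14% of the parent height
  tb <- hand_table("wt/wt", "wt/wt")
  pos <- .str_sizes(cfg, "FGA", "23")
  tb$peaks$height[tb$peaks$dye == "green" & tb$peaks$size == pos] <- 1120L
  v <- assess_contamination(call_sample(tb, cfg), cfg)
  expect_true(v$detected)
  expect_equal(v$criteria_hit, "STUTTER_EXCESS")
  expect_match(v$evidence$explanation, "14.0% of parent")
})

test_that("a low F5 het ratio raises RATIO_IMBALANCE (delegated to caller)", {
  tb <- hand_table("var/wt", "wt/wt")
  tb$peaks$height[tb$peaks$size == 129] <- 3000L
  v <- assess_contamination(call_sample(tb, cfg), cfg)
  expect_true(v$detected)
  expect_equal(v$criteria_hit, "RATIO_IMBALANCE")
})

test_that("no false positives across the genotype sweep when spreads are zero", {
  # With the ratio/stutter SDs at 0, every simulated value sits exactly on
  # its mean, isolating the decision logic from the intentional ~2% tail
  # re-test rate of a mean +/- 2 SD rule.
  p0 <- sim_params(het_ratio_f5 = c(mean = 0.61, sd = 0),
                   het_ratio_f2 = c(mean = 0.67, sd = 0),
                   stutter_fga = c(mean = 0.076, sd = 0),
                   stutter_se33 = c(mean = 0.076, sd = 0))
  set.seed(19)
  freqs <- demo_str_frequencies()
  states <- c("wt/wt", "var/wt", "var/var")
  for (s5 in states) for (s2 in states) {
    gt <- sample_genotype(freqs, f5 = s5, f2 = s2)
    tb <- synthesize(mixture_spec(gt), params = p0, cfg = cfg,
                     noise = FALSE)
    v <- assess_contamination(call_sample(tb, cfg), cfg)
    expect_false(v$detected)
  }
})

test_that("identity comparison matches runs of the same individual only", {
  a <- call_sample(hand_table("var/wt", "wt/wt"), cfg)
  b <- call_sample(hand_table("wt/wt", "wt/wt"), cfg)  # same STRs by builder
  cmp <- compare_identity(a, b)
  expect_true(cmp$match)
  expect_equal(nrow(cmp$comparison), 2)
  # different STR genotype -> mismatch, symmetric
  tb2 <- hand_table("wt/wt", "wt/wt")
  shift <- tb2$peaks$dye == "green"
  tb2$peaks$size[shift] <- tb2$peaks$size[shift] + 8  # FGA 23/26 instead
  c2 <- call_sample(peak_table("other", "r1", tb2$peaks), cfg)
  expect_false(compare_identity(a, c2)$match)
  expect_false(compare_identity(c2, a)$match)
})

test_that("pairs with no co-called locus are incomparable, not mismatched", {
  a <- call_sample(make_table(green = c("120" = 8000),
                              black = c("276" = 7000)), cfg)
  b <- call_sample(make_table(blue = c("329" = 8000),
                              black = c("276" = 7000)), cfg)
  cmp <- compare_identity(a, b)
  expect_true(is.na(cmp$match))
  expect_setequal(cmp$excluded_loci, c("FGA", "SE33"))
})

test_that("random pairs almost never match (empirical vs HWE expectation)", {
  set.seed(5)
  freqs <- demo_str_frequencies()
  n <- 1000
  matches <- 0
  for (i in seq_len(n)) {
    g1 <- sample_genotype(freqs)
    g2 <- sample_genotype(freqs)
    same <- identical(sort(g1$fga), sort(g2$fga)) &&
      identical(sort(g1$se33), sort(g2$se33))
    matches <- matches + same
  }
  # expected rate = sum over genotypes of freq^2, per locus, multiplied:
  p_match <- function(f) {
    hom <- sum(f^2 * f^2)
    het <- 0
    nm <- names(f)
    for (i in seq_along(f)) for (j in seq_along(f)) if (i < j)
      het <- het + (2 * f[i] * f[j])^2
    hom + het
  }
  expected <- p_match(freqs$FGA) * p_match(freqs$SE33)
  expect_lt(expected, 1e-3)
  expect_lte(matches, stats::qbinom(0.999, n, expected) + 1)
})

test_that("random match probability follows the Hardy-Weinberg product rule", {
  f <- structure(list(L1 = c(a = 0.2, b = 0.3), L2 = c(a = 0.2, b = 0.8)),
                 class = "freq_table")
  # hand arithmetic: 2*0.2*0.3 * 0.2^2 = 0.0048
  expect_equal(random_match_probability(list(L1 = c("a", "b"),
                                             L2 = c("a", "a")), f), 0.0048)
  expect_equal(random_match_probability(list(L1 = c("b", "b")),
                                        structure(list(L1 = c(b = 1)),
                                                  class = "freq_table")), 1)
  # missing allele: error without a floor, floored with one
  expect_error(random_match_probability(list(L1 = c("z", "b")), f), "absent")
  expect_equal(random_match_probability(list(L1 = c("z", "b")), f,
                                        min_freq = 0.001), 2 * 0.001 * 0.3)
})

test_that("RMP never exceeds any per-locus genotype frequency", {
  freqs <- demo_str_frequencies()
  set.seed(17)
  for (i in 1:50) {
    g <- sample_genotype(freqs)
    gt <- list(FGA = g$fga, SE33 = g$se33)
    rmp <- random_match_probability(gt, freqs)
    per_locus <- vapply(names(gt), function(loc)
      random_match_probability(gt[loc], freqs), numeric(1))
    expect_lte(rmp, min(per_locus) + 1e-12)
  }
})

test_that("most frequent two-locus genotype lands in the expected RMP range", {
  freqs <- demo_str_frequencies()
  top2 <- function(f) names(sort(f, decreasing = TRUE))[1:2]
  gt <- list(FGA = top2(freqs$FGA), SE33 = top2(freqs$SE33))
  rmp <- random_match_probability(gt, freqs)
  expect_gt(rmp, 1e-4)
  expect_lt(rmp, 1e-2)
})
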