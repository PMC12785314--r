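---
title: "Interpreting the multiplex PCR-RFLP thrombophilia assay: models, thresholds and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpreting the multiplex PCR-RFLP thrombophilia assay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rflpmx)
```

## The interpretation problem

Factor V Leiden (*F5* c.1601G>A) and prothrombin *F2* G20210A are the two
inherited thrombosis risk factors detected by DNA testing. The assay this
package interprets genotypes both in one multiplex PCR: FV Leiden abolishes
an MnlI restriction site, so after digestion a wild-type *F5* allele yields
a 92 bp labelled fragment and a variant allele 129 bp; G20210A creates a
HindIII site through a mutagenic primer, so wt sizes at 246 bp and the
variant at 226 bp. Because an apparently wild-type pattern is exactly what
an *undigested* reaction produces, the design co-amplifies controls: the
*F5* amplicon carries a second, mandatory MnlI site (its uncut 289 bp form
must vanish), and an *FGA* intron 1 fragment carries a mandatory HindIII
site (uncut 339 bp must vanish, cut 276 bp must appear). Two highly
polymorphic tetranucleotide STRs, FGA and SE33, ride along on their own dye
channels for per-sample identity monitoring and contamination detection.

The input to interpretation is not a trace but a discrete peak table —
(dye, apparent size in bp, height in RFU) — as exported by fragment-analysis
software. All sizes here are *apparent* sizes against the instrument's size
standard and are treated as exact configured constants; no mobility
correction is modelled.

## The decision procedure

`call_sample()` composes four steps, in order:

1. **Digestion validation** (`check_digestion()`). MnlI is valid iff no
   peak ≥ the calling threshold sits at 289 ± 1 bp on the red channel.
   HindIII is valid iff 339 ± 1 bp (black) is empty *and* 276 ± 1 bp is
   occupied: an empty channel proves nothing, so the missing cut control
   also invalidates the check. An empty peak table therefore yields MnlI
   "valid" (nothing uncut) but HindIII invalid.
2. **Biallelic calls** (`call_biallelic()`), gated on the relevant control.
   A failed digest forces `no_call` — never a genotype from an unvalidated
   digest, because the uncut *F2* amplicon sizes like its wt fragment and
   would masquerade as wt/wt. With a valid digest, fragment presence above
   threshold determines wt/wt, var/wt or var/var; a heterozygote records
   the ratio variant height / wt height and is flagged `RATIO_LOW_*` below
   the 0.49 floor.
3. **STR calls** (`call_str()`), described below.
4. **Verdict**: `FAIL` on any undigested-control flag, `RETEST` on ratio or
   contamination flags, `PASS` on an empty flag set.

### STR allele calling and stutter

Candidate peaks (≥ threshold on the locus dye) are binned to the allele
ladder and classified tallest-first:

* a peak one repeat unit (4 bp) below an already-accepted, strictly taller
  allele at ≤ 11% of its height is **stutter** (the PCR slippage artifact);
* otherwise, a peak at ≥ 50% of the tallest peak is accepted as a true
  **allele**, up to the diploid expectation of two;
* everything else is an unexplained **extra** peak. Extras at a stutter
  position keep the offending height fraction — they are stutter-height
  exceedances, the signature of a contaminant allele hiding on a stutter
  position.

The 50% second-allele acceptance floor (`str_second_allele_min`) is a
design choice this package adds: without it, a faint contaminant peak on an
otherwise homozygous profile would be accepted as a genuine second allele
and the extra-allele criterion could never fire. Fifty percent mirrors the
re-test floor used for the biallelic ratios; genuine sister alleles of a
heterozygote amplify near parity, while mixture components at the ratios
the validation study uses (1:10, 1:20) sit an order of magnitude lower, so
the gap between the two populations is wide. A single accepted allele is
reported as a homozygote (duplicated label).

Sizes outside the ladder range (± 0.5 bp) are reported off-ladder and
flagged, never raised as errors: artifact peaks can land anywhere and a
caller that stops on them is useless.

### The allele ladder

Each STR locus maps repeats to size linearly: `size(r) = size_at_min +
4 × (r − r_min)`, with microvariants (x.1, x.2, x.3 in forensic notation)
occupying the 1 bp lattice between full repeats. The ladder is anchored at
the smallest allele (FGA allele 14 at 92 bp post-MnlI, SE33 allele 4.2 at
279 bp) and the locus's observed size range is *computed* from the ladder
endpoints (FGA 92–237 bp, SE33 279–417 bp). Published range figures for
such loci are typically a few bp wider than the arithmetic span, since they
quote the extremes of margin-padded bins; the computed span is the one the
linear map can actually support, so it wins here.

## Thresholds and their provenance

| threshold | default | origin |
|---|---|---|
| `allele_call_rfu` | 150 RFU | 3 × the 50 RFU noise ceiling observed in blank runs |
| `noise_ceiling_rfu` | 50 RFU | highest background peak in formamide blanks |
| `saturation_rfu` | 32 000 RFU | instrument ceiling; off-scale peaks are clipped and warned about, not rejected |
| `het_ratio_min_f5`, `het_ratio_min_f2` | 0.49 | mean − 2 SD of the het ratio distributions 0.61 ± 0.06 and 0.67 ± 0.09; `threshold_from_moments()` reproduces the derivation |
| `stutter_max_fraction` | 0.11 | mean + 2 SD of the 7.6 ± 1.8% stutter distribution, rounded to integer percent |
| `stutter_k` | 2 | SD multiplier; 3 appears in some protocol variants, configurable |
| `size_match_tol` | 1.0 bp | single-base resolution of POP7 capillary electrophoresis |
| `str_bin_tol` | 0.5 bp | STR ladder bins are 1 bp apart |
| `str_second_allele_min` | 0.5 | see above |

Two documentary notes. First, 150 RFU is the interpretation cut-off used
throughout; a 250 RFU "arbitrary detection threshold" also circulates for
this instrument family and the two are not reconciled — 150 is the default
and the field is configurable. Second, the ratio floors are one-sided: only
the *lower* cut is specified (high ratios are not a described failure
mode), so no upper bound is enforced.

By construction, a mean ± 2 SD rule re-tests ≈ 2.3% of genuinely clean
heterozygotes per ratio, and ≈ 2% of genuine stutter peaks per allele
exceed the 11% ceiling. That is the assay's intrinsic re-test rate, not an
error; tests that assert a *zero* false-positive rate do so with the spread
parameters set to zero, isolating the decision logic from this intentional
tail behaviour.

## The simulator

`synthesize()` generates peak tables with the assay's statistical
structure; it is the package's test bed and makes every validation study
re-runnable without instrument data.

* **Heights.** Each locus draws an allele unit height from a log-normal
  with median 8000 RFU and log-SD 0.3, placing peaks comfortably inside the
  250–32 000 RFU working range; a homozygous (or wild-type) product gets
  twice the unit height, mirroring the summed contribution of two alleles.
  Coincident sizes are summed, then clipped at saturation.
* **Het ratios.** The variant peak of a heterozygote is the wt height times
  a draw from N(0.61, 0.06²) (*F5*) or N(0.67, 0.09²) (*F2*), truncated to
  (0, 1.5) to exclude pathological values; truncation at these parameters
  is a > 10 SD event, so the configured moments are preserved.
* **Stutter.** Every STR allele spawns a peak one repeat unit below at a
  fraction drawn from N(7.6%, 1.8²%) (FGA) or N(7.6%, 1.6²%) (SE33),
  truncated at 0; stutter below 1 RFU is dropped.
* **Noise.** A Poisson(3) count of background peaks, uniform heights on
  (1, 49) RFU, uniform sizes over the read window, random dye. By
  construction no noise peak can reach the 150 RFU calling threshold.
* **Mixtures.** A contaminant genotype contributes the same peak structure
  with unit heights scaled linearly by the ng:ng ratio (1:20 → 5% of the
  primary's locus height). Linear scaling treats the DNA amount as the
  controlled variable; PCR competition between templates is out of scope.
* **Digestion failure.** The `mnl` mode replaces the *F5* products with the
  uncut 289 bp peak; `hind` replaces the 276 bp control with 339 bp and
  collapses all *F2* product onto the 246 bp uncut size. The mobility shift
  of *uncut* FGA STR fragments (roughly +56 bp) is not modelled — in a
  failed digest the verdict is already FAIL from the control peaks, so the
  STR positions are immaterial to the decision path being tested.
* **Determinism.** All draws run through R's global RNG; a fixed seed gives
  byte-identical CSV output, which the test suite asserts.

STR genotypes are drawn under Hardy–Weinberg equilibrium from a frequency
table; the packaged `str_frequencies_demo.csv` is a *synthetic*
demonstration table with realistic European-like FGA/SE33 frequencies, not
a population reference — random-match probabilities computed from it are
order-of-magnitude illustrations only.

### What the simulator does not emulate

Continuous electropherogram traces, baseline drift, dye pull-up between
channels, size-calling error (apparent sizes are exact), preferential
amplification of short alleles, n+1 or n−2 stutter, allele dropout at low
template, and PCR competition in mixtures. Consequently, passing in-silico
studies demonstrate that the *decision logic* is faithful to the rules and
thresholds — not that the assay achieves these rates on instrument data;
the wet-lab validation answers that separately.

## In-silico validation studies

`run_validation_study()` re-runs, at desk scale:

* **`concordance`** — the 62-sample accuracy cohort (31 double wild-type,
  16 *F5* heterozygotes, 14 *F2* heterozygotes, 1 *F5* homozygote),
  simulated cleanly, called, and tabulated per category with Wilson CIs.
* **`mixture_1to10` / `mixture_1to20`** — 30 two-person mixtures in the
  validation layout (11 wt-into-wt, 7 wt-into-*F5*-het, 2 wt-into-*F2*-het,
  5 *F5*-het-into-wt, 5 *F2*-het-into-wt), each with independently drawn
  STR genotypes, assessed by the three contamination criteria: extra STR
  allele, stutter exceedance, ratio imbalance.
* **`ratio_stats` / `stutter_stats`** — parameter recovery: the empirical
  mean ± SD of called het ratios (default n = 1000) or called stutter
  fractions (n samples ≈ 4n fractions) against the configured moments.

Problem sizes were chosen so each study answers its statistical question
at interactive speed: 62 and 30 match the original designs; 1000
heterozygotes put the standard error of the mean ratio near 0.002, an
order of magnitude inside the ± 0.01 acceptance band.

The Wilson score interval was chosen for all proportion CIs because at full
success (k = n) it has the closed form n/(n + z²) — at 30/30 a lower bound
of 0.8865, printing as 0.89, which matches the published detection CIs;
Clopper–Pearson would print 0.88. `stats::prop.test(correct = FALSE)`
serves as an independent cross-check in the tests.

## Contamination detection: scope and blind spots

`assess_contamination()` reports which of the three criteria fired, with
per-peak evidence. Three limitations are inherent and documented rather
than patched:

* a contaminant sharing all four STR alleles (or hiding entirely on stutter
  positions *below* the ceiling) is undetectable by design; the ratio
  criterion is the only remaining tripwire;
* no quantitative mixture-ratio estimate is produced — too many mechanisms
  (preferential amplification, injection bias) influence peak imbalance for
  a height ratio to identify the mixing fraction;
* detection degrades with dilution simply because contaminant peaks fall
  below the 150 RFU interpretation limit; the monotone sweep in the test
  suite (1:100 → 1:5) shows exactly this threshold behaviour.

Identity comparison (`compare_identity()`) is deliberately strict: allele
multisets must agree at every co-called locus; pairs with no co-called
locus are "incomparable", a distinct outcome from a mismatch, so a failed
STR channel can never silently vouch for sample identity.

## Degenerate inputs and tie-breaks

* `match_peak()` prefers height, then smaller size deviation, then smaller
  size — fully deterministic on ties.
* Empty peak tables, empty channels, and three-or-more allelic peaks all
  produce defined outcomes (no_call + LOW_SIGNAL, HindIII-invalid,
  extras) rather than errors.
* Cut positions falling outside a sequence are dropped silently in the
  digestion engine (site too close to an end); fragments always tile the
  input exactly, which the property tests assert against a brute-force
  scanner on random sequences.
* Concordance categories with zero samples are omitted from the summary
  rather than dividing by zero.
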