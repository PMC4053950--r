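---
title: "Imperfect centered miRNA binding sites: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imperfect centered miRNA binding sites: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Most validated miRNA-mRNA interactions run through the seed: Watson-Crick
pairing of miRNA positions 2-8 with the target. A second mode pairs the
central region of the miRNA instead - an 11-nt duplex beginning at miRNA
position 3, 4 or 5 ("centered sites"). Perfect centered sites are rare in
transcriptomes, but if G:U wobble pairs and a single internal mismatch are
tolerated, such *imperfect* centered sites become abundant, and their
association with experimentally captured targets is a testable question.
`censite` implements that test end to end: site scanning, pull-down
enrichment calling, association statistics, and the positional analysis of
sites inside AGO-bound CLIP peaks - driven by a synthetic-data generator
with machine-readable ground truth, so every stage is verifiable without
any external data.

# Site definitions and the scanner

Sequences are RNA, 5'→3'; transcript coordinates are 0-based half-open;
miRNA positions are the only 1-based quantity. Pairing is antiparallel:
window position $j$ (1-based along the miRNA) pairs with site position
$12-j$ of an 11-nt site read 5'→3' on the mRNA. A pair is Watson-Crick
(A:U, U:A, G:C, C:G), wobble (G:U, U:G), or a mismatch.

Seed classes follow the TargetScanS conventions and admit no wobble or
mismatch: **8mer** (match to positions 2-8 plus target A opposite position
1), **7mer-m8** (match 2-8), **7mer-A1** (match 2-7 plus the A). 6mers are
not counted. Centered sites come in four classes by wobble use and
mismatch count: **WC 0MM**, **GU 0MM**, **WC 1MM**, **GU 1MM**.

Decisions the class definitions leave open, and what this package does:

* **"Middle of the site."** The single tolerated mismatch may occupy any
  interior window position (2-10 of the 11-mer), never position 1 or 11.
  A mismatch at a terminal position would shorten the duplex rather than
  interrupt it, and the central pairing zone is what distinguishes these
  sites; both the mismatch budget (`max_mm`) and the interior rule
  (`interior_only`) are parameters of `scan_params()`.
* **Wobble budget.** Unlimited G:U pairs qualify a site for the GU
  classes (`max_gu = Inf` by default, configurable).
* **Precedence and merging.** Classes are mutually exclusive labels:
  WC 0MM > GU 0MM > WC 1MM > GU 1MM, and 8mer > 7mer-m8 > 7mer-A1. One
  locus can match several windows and several offsets; overlapping hits
  of one miRNA within one family are merged into a single site carrying
  the most stringent class (ties: smallest start, then smallest window
  start), so downstream counts never double-count a locus. Raw unmerged
  hits are available with `scan_params(merge_overlaps = FALSE)`.
* **Region assignment.** Each site belongs to the region (5'UTR, CDS,
  3'UTR) containing its midpoint; sites are never split across regions.

The scanner encodes the concatenated transcriptome over the integer
alphabet A/C/G/U with an `N` separator that can never pair, and evaluates
every offset against every window in C++ (`src/scan.cpp`). The test suite
holds it to an independently coded per-position enumeration oracle over
random transcriptomes and to exact recovery of planted sites.

# Enrichment calling

The pull-down analysis takes replicate intensity matrices
(PULLDOWN/CONTROL), keeps probes detected (detection p < 0.01) in *every*
control sample, log2-transforms and quantile-normalises, and tests each
probe with an empirical-Bayes moderated t statistic in the enrichment
direction only (upper tail). Per-probe variances $s_g^2$ with $d$ degrees
of freedom are shrunk toward a prior $(d_0, s_0^2)$ fitted by moment
matching on $\log s_g^2$ (digamma/trigamma relations, with the trigamma
inversion solved by bracketed root finding):

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d\, s_g^2}{d_0 + d},\qquad
  t_g = \frac{\overline{x}_{g,\mathrm{pd}} - \overline{x}_{g,\mathrm{ctl}}}
            {\tilde s_g \sqrt{1/n_1 + 1/n_2}},$$

on $d_0 + d$ degrees of freedom. If the trigamma inversion fails the
caller falls back to the ordinary t with a warning. The two limits are
exact and tested: $d_0 = 0$ reproduces the ordinary two-sample t, and
$d_0 \to \infty$ a z statistic with variance $s_0^2$. Benjamini-Hochberg
adjustment (via `p.adjust`) at 5% FDR defines enrichment; targets are the
transcripts exactly matched by enriched probes, and transcripts also
matched by a retained non-enriched probe are set aside as ambiguous.

The quantile-normalisation stack here deliberately replaces the
variance-stabilising-transform + robust-spline pipeline used with real
bead arrays: it is deterministic, dependency-free and adequate for
synthetic data, but it is *not* the same normalisation, so probe counts
from published bead-array experiments are not comparable targets for this
artifact. One consequence worth knowing: quantile normalisation removes
the global component of the pull-down shift, so when the simulation gives
most transcripts a slightly negative shift and a minority a positive one,
transcripts just below the truth threshold are pushed over it and the
realised false-discovery proportion against simulation truth exceeds the
nominal level. The FDR-calibration experiments (10% enriched probes on a
flat background, 200 runs) measure the caller itself and show mean
realised FDP at or below the nominal 5% (the acceptance band allows
0.06).

# Association statistics

* **2x2 exact tests.** `fisher_exact_upper()` computes the exact
  hypergeometric upper tail $P[X \ge w]$ conditioned on the margins. The
  odds ratio is the sample cross-product ratio $(wz)/(xy)$ with the
  Haldane-Anscombe +0.5 applied to all cells when any cell is zero
  (flagged), and a Woolf logit 95% CI - not the conditional-MLE odds
  ratio some software reports, so printed ORs from other tools can differ
  slightly while the p-value is identical; the suite checks the p-value
  against full enumeration for every table with margins up to 30.
* **Logistic model.** For transcript $i$,
  $\mathrm{logit}\,p_i = \beta_0 + \sum_{a,b} \beta_{a,b}\, x_{a,b,i}$,
  where $x_{a,b,i}$ counts class-$a$ sites in region $b$ (or their
  density, sites per kilobase of the region - "density" is otherwise
  undefined and this is the documented choice). The fit is maximum
  likelihood by IRLS (`glm.fit`), Wald tests come from the observed
  information, and Nagelkerke's $r^2$ rescales the Cox-Snell
  $1 - \exp(2(L_0 - L_1)/n)$ by its maximum. All three regions are
  available as covariates; the headline analyses use CDS and 3'UTR, and a
  canonical-only mode keeps one (longest) transcript per gene to avoid
  probe-level pseudo-replication. Genuine complete separation (a
  covariate whose ranges for the two outcomes do not overlap) is an
  error naming the covariate; quasi-separation from sparse count columns
  is tolerated and surfaced through the convergence flag.
* **Distribution shift.** `ks_shift_test()` is the one-sided two-sample
  Kolmogorov-Smirnov test that the in-set log fold changes are
  stochastically greater (asymptotic by default, exact behind a flag).
* **Shared targets.** For a related miRNA pair (e.g. a canonical miRNA
  and its shifted isomiR, which share centered but not seed sequence),
  `isomir_shared_site_test()` asks whether jointly targeted transcripts
  carry a site class more often than transcripts unique to either
  target set, optionally after removing transcripts with multiple
  distinct site types so each transcript carries one attributable class.
* Raw FET p-values are reported without multiple-testing adjustment by
  default (BH is available), matching how such per-class tables are
  usually presented.

# Peak analysis

For AGO CLIP peaks, `site_offsets()` scans a fixed window (default
half-width 200 nt - the window is a parameter, as published analyses
rarely state theirs) around each peak center and records the signed
offset of each site midpoint (midpoint, not 5' end, so 7-, 8- and 11-mers
are treated symmetrically). Concentration at the center is summarised by
the population-moment excess kurtosis $g_2 = m_4/m_2^2 - 3$, and site
presence is tested against the differential flag with the one-sided exact
test. Closed forms anchor the estimator in the tests: a symmetric
two-point sample gives exactly $-2$, uniform draws $-1.2$, normal draws
$0$.

A caveat the simulation makes visible: imperfect centered sites (GU 1MM
especially) have an appreciable background match rate, so offsets pooled
over peaks mix a sharp planted component with a uniform background and
the pooled kurtosis for the permissive classes can be negative even when
planting is concentrated. The seed classes, with their tiny background
rate, show the positive kurtosis cleanly; restricting the centered scan
to the 0MM classes does the same.

# The synthetic-data generator

`sim_config()` fixes the emulated study conditions; all stages are pure
functions of (config, seed), with per-stage seeds derived from the master
seed so stages reproduce independently of execution order.

* **Transcriptome**: 5,000 transcripts; log-normal region lengths
  (medians 150/1,200/800 nt for 5'UTR/CDS/3'UTR, log-sd 0.5/0.45/0.6),
  i.i.d. uniform base composition; 20% of transcripts belong to
  two-isoform genes and the longest isoform per gene is canonical.
* **Planting**: sites of all seven classes at Poisson rates per
  (class, region) - 0.12 per transcript in the 3'UTR, 0.06 in the CDS,
  0.02 in the 5'UTR. The planted fragment realises exactly the requested
  class; flanking guard bases force mismatches in the shifted alignments
  that the neighbouring windows would otherwise form, so the merged scan
  reports exactly the planted coordinates. After planting, the whole
  transcriptome is re-scanned and the rare transcript whose planted site
  was absorbed by chance context is regenerated; the shipped truth table
  is therefore scanner-consistent by construction.
* **Pull-down**: one probe per transcript; control replicates are
  baseline plus noise (log2 sd 0.35, 3+3 replicates), pull-down
  replicates add a shift *linear in the scanned site counts*,
  $\Delta_i = \beta_0 + \sum_{a,b}\beta_{a,b} x_{a,b,i}$, with true
  status defined by the deterministic part being positive. Scanned - not
  merely planted - counts define the truth, so accidental background
  sites carry their effects and recovery checks are exact. Per-site
  effects are strongest for seeds in the 3'UTR (1.3) and decline through
  the centered classes (0.6-0.9 in the 3'UTR, roughly half in the CDS);
  $\beta_0 = -2$ sets the true-target fraction near one fifth of the
  transcriptome, the scale seen in miRNA pull-downs. A per-probe random
  effect is available (`probe_effect_sd`) but defaults to 0 to keep the
  truth unambiguous. The generative model is deliberately the linear
  threshold form rather than the logistic itself: it gives the caller
  realistic replicate structure while the logistic fit estimates a
  monotone transform of the planted effects, so association analyses are
  checked on sign and ordering. For the regression parameter-recovery
  studies, `simulate_enrichment_status()` instead draws status directly
  from the logistic model on the scanned covariates, making the fitted
  model exactly correctly specified.
* **Peaks**: 4,000 peaks of 401 nt, 10% differential (about 400, the
  scale of a differential AGO2 HITS-CLIP comparison); differential peaks
  carry a planted site at a Gaussian offset (sd 8 nt) from the center
  with probability 0.95, unchanged peaks carry background sites at rate
  0.03 at uniform offsets.

What the generator does *not* emulate: array probe physics (affinity,
saturation, background correction), sequence composition beyond i.i.d.
bases (no codon structure, GC gradients or repeats), secondary structure
and site accessibility, and conservation. Passing tests therefore say the
*methods* are implemented correctly and calibrated on data satisfying
their assumptions - not that imperfect centered sites behave identically
in any particular living cell.

# Numerical and testing choices

* Problem sizes in the routine test suite: the scanner oracle runs on
  100 random 2-kb transcripts against 5 miRNAs; planted-site recovery on
  roughly 1,100 planted sites; the exact-test enumeration covers every
  2x2 table with margins up to 30 (about 150,000 tables, tolerance
  1e-12); FDR calibration uses 200 simulated experiments of 1,000 probes;
  parameter recovery uses 50 seeded 5,000-transcript transcriptomes with
  four independent status draws each (the extra draws reduce the
  Monte-Carlo error of the coverage estimate; the coverage criterion
  itself stays at 90% against a nominal 95.4%).
* Intercept-only logistic fits reproduce the closed form
  $\beta_0 = \mathrm{logit}(\bar y)$ to 1e-8 and the log-likelihood
  gradient at any solution is below 1e-6 in max-norm.
* Ties in BH adjustment are value-ties and resolve identically whatever
  the input order; outputs are written with stable column order, fixed
  formats (6 significant digits, scientific notation for p/q), and LF
  endings, so a fixed seed gives byte-identical output trees.
* Degenerate inputs have defined behaviour throughout: zero-length
  regions flag densities as zero-length rather than dividing by zero;
  transcripts shorter than a site scan to an empty result; miRNAs of
  13-14 nt carry a partial window set with a warning and below 13 are an
  error; constant vectors have no kurtosis (error) rather than NaN.

# Known limitations

* The enrichment normalisation is a simplification (above); analyses of
  real bead-array data should substitute the platform's own pipeline
  upstream and enter at `moderated_t_enrichment()`.
* The odds-ratio convention (sample OR, Haldane-Anscombe, Woolf CI)
  differs from conditional-MLE intervals; p-values agree.
* The scanner deliberately ignores 3'-supplementary/3'-compensatory
  sites, G-bulge sites, seed-like sites with wobble, thermodynamic
  accessibility and conservation scoring.
* `fit_logistic_sites()` is plain ML: no penalisation, no mixed effects,
  no cross-validation; with very sparse covariates, Wald intervals carry
  their usual small-count caveats.
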