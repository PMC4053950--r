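# censite

Scanning, statistics and simulation for **imperfect centered miRNA
binding sites**.

Most characterised miRNA-mRNA interactions pair the miRNA *seed*
(positions 2-8) with the target. A complementary mode pairs the central
region instead: an 11-nt duplex starting at miRNA position 3, 4 or 5
(a *centered site*). Perfect centered sites are rare, but once G:U wobble
pairs and a single internal mismatch are tolerated, imperfect centered
sites are common - and whether they mediate real interactions can be
tested with pull-down enrichment data and AGO CLIP peaks. `censite` is a
tested, reusable implementation of that analysis for computational
biologists studying miRNA targeting: site scanning, enrichment calling,
association statistics, peak-offset analysis, and a fully seeded
synthetic-data generator so the whole pipeline runs and is verifiable
without any external data.

## What it computes

**Site classes.** Seed matches follow TargetScanS conventions: 8mer,
7mer-m8, 7mer-A1 (no wobble, no mismatch; 6mers not counted). Centered
sites are 11-nt antiparallel duplexes - window position *j* pairs site
position 12-*j* - in four mutually exclusive classes: WC 0MM, GU 0MM,
WC 1MM, GU 1MM (wobble use x one interior mismatch, positions 2-10 of
the window only). Overlapping hits merge to the most stringent class.

**Enrichment.** Probes detected in all control samples (detection
p < 0.01) are log2 + quantile normalised and tested per probe with an
empirical-Bayes moderated t in the enrichment direction: the posterior
variance is `(d0*s0^2 + d*s^2)/(d0 + d)` with the prior `(d0, s0^2)`
fitted by moment matching on `log s^2`; p-values are upper-tail on
`d0 + d` df, BH-adjusted at 5% FDR. Targets are transcripts exactly
matched by enriched probes; transcripts also matched by a non-enriched
probe are ambiguous and excluded.

**Association.** One-sided Fisher exact tests (hypergeometric upper tail,
sample odds ratio `(w*z)/(x*y)` with Haldane-Anscombe correction and
Woolf 95% CI) relate site presence to target status, per class and
optionally after excluding transcripts with multiple site types. The
logistic model

```
logit p_i = b0 + sum_{a,b} b_{a,b} * x_{a,b,i}
```

regresses enrichment status on the count (or density, sites/kb) of
class-*a* sites in region *b* (5'UTR/CDS/3'UTR), with Wald tests and
Nagelkerke r². One-sided Kolmogorov-Smirnov tests compare pull-down
log-fold-change distributions, and shared-target comparisons ask whether
transcripts targeted by two related miRNAs (isomiR pairs share centered
but not seed sequence) are enriched for a site class.

**Peaks.** Signed offsets of site midpoints from AGO-peak centers within
a ±200-nt window, summarised by excess kurtosis `g2 = m4/m2^2 - 3`
(positive = concentrated at the center), plus a one-sided exact test of
site presence in differential versus unchanged peaks.

## Worked example

The numbered scripts under `analysis/` run the full study on synthetic
data (about two minutes end to end) and write their tables under
`results/`:

```sh
Rscript analysis/01_simulate.R      # transcriptome + pull-down + peaks
Rscript analysis/02_scan_sites.R    # seed/centered scan + count table
Rscript analysis/03_enrichment.R    # moderated t, FDR, target calling
Rscript analysis/04_associations.R  # FETs, logistic fits, coverage, KS
Rscript analysis/05_peaks.R         # offsets, kurtosis, differential FET
```

Representative output (seed 20260921):

```
transcriptome: 5000 transcripts, 4500 genes, 6991 planted sites
6991 of 6991 planted sites recovered at their exact class and position
4750 of 5000 probes detected in all control samples
moderated t: prior df d0 = 38.60, prior variance s0^2 = 0.1248
1147 probes enriched at 5% FDR
site-type FETs (non-exclusive): OR range 2.14-6.17
logistic (count): n = 4750, LRT p = 0, Nagelkerke r2 = 0.7305
logistic (density): n = 4750, LRT p = 3.37e-297, Nagelkerke r2 = 0.3962
targets with a seed site: 92.2%; with any seed or centered site: 100.0%
seed sites: n = 641, excess kurtosis g2 = 0.99, differential-peak FET OR = 244.99 (p = 0)
centered sites: n = 797, excess kurtosis g2 = 0.34, differential-peak FET OR = 127.11 (p = 1.72e-275)
```

Reading this: every planted site was re-found at its exact class and
position; about a quarter of detected transcripts are called targets at
5% FDR; every site class is over-represented among targets (odds ratios
2.1-6.2); site counts explain target status far better than densities;
targets are almost fully accounted for by at least one seed or centered
site; and sites in AGO peaks cluster at peak centers (positive excess
kurtosis) and concentrate in differential peaks. Because the generator
plants the effects, these numbers are strong by construction - their
point is that the pipeline recovers the planted structure, with
magnitudes on synthetic scales, not that any real transcriptome behaves
this way.

The same pipeline runs in one call:

```r
library(censite)
out <- run_pipeline(sim_config(seed = 1), out_dir = "results/run1")
out$summary
```

Programmatic entry points: `scan_sites()` / `scan_centered()` /
`scan_seed()`, `site_count_table()`, `detection_filter()`,
`normalize_expression()`, `moderated_t_enrichment()`, `call_targets()`,
`fisher_exact_upper()`, `site_type_enrichment()`, `fit_logistic_sites()`,
`ks_shift_test()`, `isomir_shared_site_test()`, `site_offsets()`,
`excess_kurtosis()`, `differential_peak_site_test()`, and the generator
family `sim_config()`, `generate_transcriptome()`, `plant_site()`,
`simulate_pulldown()`, `simulate_peaks()`. The methods vignette
(`vignettes/centered-sites.Rmd`) documents the models, parameter
defaults, and the design decisions behind them.

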