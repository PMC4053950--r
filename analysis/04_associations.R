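#!/usr/bin/env Rscript
# Stage 4: associate predicted sites with enrichment status.  Per-class
# one-sided Fisher exact tests (with and without exclusive-type
# filtering), the logistic model on site counts and on site densities
# (all transcripts and canonical-only), the site-coverage proportions
# among targets, and a KS shift test of pull-down log fold change for
# site carriers.

suppressPackageStartupMessages(library(censite))

counts <- read_tsv("results/site_counts.tsv")
class(counts) <- c("site_count_table", "data.frame")
targets <- read_tsv("results/targets.tsv")$transcript_id
enr <- read_tsv("results/enrichment.tsv")
probe_map <- read_tsv("results/data/probe_map.tsv")

tested <- probe_map$transcript_id[match(enr$probe_id, probe_map$probe_id)]
background <- tested

fet_rows <- list()
for (excl in c(FALSE, TRUE)) {
  for (cl in SITE_CLASSES) {
    r <- site_type_enrichment(targets, background, counts, cl,
                              exclusive = excl)
    fet_rows[[length(fet_rows) + 1L]] <- data.frame(
      site_class = cl, exclusive = excl, odds_ratio = r$odds_ratio,
      ci_low = r$ci_low, ci_high = r$ci_high, p = r$p, n = r$n)
  }
}
pooled <- site_type_enrichment(targets, background, counts,
                               SITE_CLASSES[4:7])
fet_rows[[length(fet_rows) + 1L]] <- data.frame(
  site_class = "ANY_CENTERED", exclusive = FALSE,
  odds_ratio = pooled$odds_ratio, ci_low = pooled$ci_low,
  ci_high = pooled$ci_high, p = pooled$p, n = pooled$n)
fet <- do.call(rbind, fet_rows)
write_tsv(fet, "results/association_fet.tsv")
message("site-type FETs (non-exclusive): OR range ",
        sprintf("%.2f-%.2f", min(fet$odds_ratio[!fet$exclusive]),
                max(fet$odds_ratio[!fet$exclusive])))

status <- counts$transcript_id %in% targets
in_bg <- counts$transcript_id %in% background
fits <- list(
  count = fit_logistic_sites(status[in_bg], counts[in_bg, ], mode = "count"),
  density = fit_logistic_sites(status[in_bg], counts[in_bg, ],
                               mode = "density"),
  count_canonical = fit_logistic_sites(status[in_bg], counts[in_bg, ],
                                       mode = "count",
                                       canonical_only = TRUE))
for (nm in names(fits)) {
  f <- fits[[nm]]
  write_tsv(f$coefficients, sprintf("results/regression_%s.tsv", nm))
  message(sprintf(
    "logistic (%s): n = %d, LRT p = %.3g, Nagelkerke r2 = %.4f", nm, f$n,
    f$lrt_p, f$r2$nagelkerke))
}
fitsum <- data.frame(model = names(fits),
                     n = vapply(fits, `[[`, numeric(1), "n"),
                     L0 = vapply(fits, `[[`, numeric(1), "L0"),
                     L1 = vapply(fits, `[[`, numeric(1), "L1"),
                     lrt_p = vapply(fits, `[[`, numeric(1), "lrt_p"),
                     nagelkerke_r2 = vapply(fits, function(f)
                       f$r2$nagelkerke, numeric(1)))
write_tsv(fitsum, "results/regression_summary.tsv")

cov <- summarize_site_coverage(intersect(targets, counts$transcript_id),
                               counts)
write_tsv(cov, "results/coverage.tsv")
message(sprintf(
  "targets with a seed site: %.1f%%; with any seed or centered site: %.1f%%",
  100 * cov$proportion[cov$what == "ANY_SEED"],
  100 * cov$proportion[cov$what == "ANY"]))

has_any <- rowSums(as.matrix(
  counts[match(tested, counts$transcript_id),
         grep("^count_", names(counts))])) > 0
ks <- ks_shift_test(enr$logFC[has_any], enr$logFC[!has_any])
message(sprintf("KS shift of logFC for site carriers: D = %.3f, p = %.3g",
                ks$D, ks$p))
write_tsv(data.frame(D = ks$D, p = ks$p), "results/ks_shift.tsv")
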