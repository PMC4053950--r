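## End-to-end driver: simulate -> scan -> enrich -> associate -> peaks.
## Deterministic given the config seed; all outputs are written as
## deterministic TSVs so two runs with the same seed are byte-identical.

#' Run the full synthetic pipeline
#'
#' Generates a transcriptome with planted sites, scans seed and centered
#' sites, simulates and analyses the pull-down (detection filter,
#' normalisation, moderated t, BH FDR, target calling), runs the
#' association analyses (per-class Fisher tests, logistic regression on
#' counts and densities, site-coverage summary), and runs the peak
#' analysis (offset profiles, kurtosis, differential-peak test) for both
#' seed and centered sites.
#'
#' @param config A \code{\link{sim_config}}.
#' @param out_dir Optional directory; when given, all inputs and results
#'   are written there as TSV/FASTA files.
#' @return Invisible list with every intermediate object and a
#'   \code{summary} data.frame of the headline quantities.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL) {
  sim <- generate_transcriptome(config)
  mirna_id <- sim$mirnas$mirna_id[1L]
  mirna <- sim$mirnas[1L, ]

  matches <- scan_sites(sim$mirnas, sim$transcripts)
  counts <- site_count_table(matches[matches$mirna_id == mirna_id, ],
                             sim$transcripts, mirna_ids = mirna_id)

  pd <- simulate_pulldown(sim, mirna_id = mirna_id, counts = counts)
  em <- detection_filter(pd$em, alpha = config$detection_alpha)
  em <- normalize_expression(em)
  enr <- moderated_t_enrichment(em, fdr = config$fdr)
  targets <- call_targets(enr, pd$probe_map, fdr = config$fdr,
                          transcripts = sim$transcripts,
                          mirna_id = mirna_id)

  tested <- pd$probe_map$transcript_id[match(enr$probe_id,
                                             pd$probe_map$probe_id)]
  background <- setdiff(tested, targets$ambiguous)

  assoc <- lapply(SITE_CLASSES, function(cl)
    site_type_enrichment(targets, background, counts, cl))
  assoc_tab <- data.frame(
    site_class = SITE_CLASSES,
    odds_ratio = vapply(assoc, `[[`, numeric(1), "odds_ratio"),
    ci_low = vapply(assoc, `[[`, numeric(1), "ci_low"),
    ci_high = vapply(assoc, `[[`, numeric(1), "ci_high"),
    p = vapply(assoc, `[[`, numeric(1), "p"),
    stringsAsFactors = FALSE)

  status <- counts$transcript_id %in% targets$targets
  in_bg <- counts$transcript_id %in% background
  fit_count <- fit_logistic_sites(status[in_bg], counts[in_bg, ],
                                  mode = "count")
  fit_dens <- fit_logistic_sites(status[in_bg], counts[in_bg, ],
                                 mode = "density")

  coverage <- summarize_site_coverage(targets$targets, counts)

  pk_seed <- simulate_peaks(config, mirna, kind = "seed")
  pk_cen <- simulate_peaks(config, mirna, kind = "centered")
  prof_seed <- site_offsets(pk_seed$peaks, mirna, kind = "seed",
                            half_window = config$half_window)
  prof_cen <- site_offsets(pk_cen$peaks, mirna, kind = "centered",
                           half_window = config$half_window)
  fet_seed <- differential_peak_site_test(pk_seed$peaks, prof_seed$presence)
  fet_cen <- differential_peak_site_test(pk_cen$peaks, prof_cen$presence)

  summary <- data.frame(
    quantity = c("n_transcripts", "n_probes_retained", "n_enriched_probes",
                 "n_targets", "pct_targets_with_seed",
                 "pct_targets_with_seed_or_centered",
                 "nagelkerke_r2_count", "nagelkerke_r2_density",
                 "seed_peak_kurtosis", "centered_peak_kurtosis",
                 "seed_peak_fet_p", "centered_peak_fet_p"),
    value = c(nrow(sim$transcripts), nrow(enr), length(targets$enriched_probes),
              length(targets$targets),
              100 * coverage$proportion[coverage$what == "ANY_SEED"],
              100 * coverage$proportion[coverage$what == "ANY"],
              fit_count$r2$nagelkerke, fit_dens$r2$nagelkerke,
              prof_seed$g2, prof_cen$g2, fet_seed$p, fet_cen$p),
    stringsAsFactors = FALSE)

  out <- list(config = config, sim = sim, matches = matches,
              counts = counts, pulldown = pd, enrichment = enr,
              targets = targets, background = background,
              association = assoc_tab, fit_count = fit_count,
              fit_dens = fit_dens, coverage = coverage,
              peaks_seed = pk_seed, peaks_centered = pk_cen,
              profile_seed = prof_seed, profile_centered = prof_cen,
              fet_seed = fet_seed, fet_cen = fet_cen, summary = summary)

  if (!is.null(out_dir)) .write_pipeline_outputs(out, out_dir)
  invisible(out)
}

.write_pipeline_outputs <- function(out, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  sim <- out$sim

  write_fasta(stats::setNames(sim$transcripts$sequence,
                              sim$transcripts$transcript_id),
              p("transcripts.fa"))
  write_fasta(stats::setNames(sim$mirnas$sequence, sim$mirnas$mirna_id),
              p("mirnas.fa"))
  write_tsv(sim$transcripts[, c("transcript_id", "gene_id", "utr5_end",
                                "cds_end", "is_canonical")],
            p("regions.tsv"))
  write_tsv(sim$truth, p("truth_sites.tsv"))
  write_tsv(out$matches, p("sites.tsv"))

  em <- out$pulldown$em
  expr <- data.frame(probe_id = rownames(em$intensities),
                     em$intensities, check.names = FALSE,
                     stringsAsFactors = FALSE)
  write_tsv(expr, p("expr.tsv"))
  write_tsv(data.frame(sample_id = colnames(em$intensities),
                       group = em$groups, stringsAsFactors = FALSE),
            p("samples.tsv"))
  det <- data.frame(probe_id = rownames(em$detection_p),
                    em$detection_p, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write_tsv(det, p("detection.tsv"))
  write_tsv(out$pulldown$probe_map, p("probe_map.tsv"))
  write_tsv(out$pulldown$truth, p("truth_pulldown.tsv"))

  write_tsv(as.data.frame(out$enrichment), p("enrichment.tsv"))
  write_tsv(data.frame(transcript_id = out$targets$targets,
                       stringsAsFactors = FALSE), p("targets.tsv"))
  write_tsv(data.frame(transcript_id = out$targets$ambiguous,
                       stringsAsFactors = FALSE), p("ambiguous.tsv"))
  write_tsv(out$association, p("association.tsv"))
  write_tsv(out$fit_count$coefficients, p("regression_count.tsv"))
  write_tsv(out$fit_dens$coefficients, p("regression_density.tsv"))
  write_tsv(out$coverage, p("coverage.tsv"))

  write_tsv(out$peaks_seed$truth, p("truth_peaks_seed.tsv"))
  write_tsv(out$peaks_centered$truth, p("truth_peaks_centered.tsv"))
  write_tsv(out$profile_seed$offsets, p("offsets_seed.tsv"))
  write_tsv(out$profile_centered$offsets, p("offsets_centered.tsv"))
  write_tsv(out$summary, p("summary.tsv"))
  invisible(out_dir)
}
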