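#!/usr/bin/env Rscript
# Stage 1: build the synthetic study.  One simulated miRNA pull-down over
# a 5,000-transcript transcriptome with sites of all seven classes
# planted at the configured per-region rates, plus AGO-peak sets for the
# seed and centered offset analyses.  All inputs and ground truth are
# written under results/data/.

suppressPackageStartupMessages(library(censite))

cfg <- sim_config(seed = 20260921)
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

sim <- generate_transcriptome(cfg)
message("transcriptome: ", nrow(sim$transcripts), " transcripts, ",
        length(unique(sim$transcripts$gene_id)), " genes, ",
        nrow(sim$truth), " planted sites")

write_fasta(setNames(sim$transcripts$sequence, sim$transcripts$transcript_id),
            "results/data/transcripts.fa")
write_fasta(setNames(sim$mirnas$sequence, sim$mirnas$mirna_id),
            "results/data/mirnas.fa")
write_tsv(sim$transcripts[, c("transcript_id", "gene_id", "utr5_end",
                              "cds_end", "is_canonical")],
          "results/data/regions.tsv")
write_tsv(sim$truth, "results/data/truth_sites.tsv")

pd <- simulate_pulldown(sim)
em <- pd$em
write_tsv(data.frame(probe_id = rownames(em$intensities), em$intensities,
                     check.names = FALSE), "results/data/expr.tsv")
write_tsv(data.frame(sample_id = colnames(em$intensities),
                     group = em$groups), "results/data/samples.tsv")
write_tsv(data.frame(probe_id = rownames(em$detection_p), em$detection_p,
                     check.names = FALSE), "results/data/detection.tsv")
write_tsv(pd$probe_map, "results/data/probe_map.tsv")
write_tsv(pd$truth, "results/data/truth_pulldown.tsv")
message("pull-down: ", sum(pd$truth$true_status), " of ", nrow(pd$truth),
        " transcripts are true targets (",
        cfg$n_rep, "+", cfg$n_rep, " replicates)")

for (kind in c("seed", "centered")) {
  pk <- simulate_peaks(cfg, sim$mirnas[1, ], kind = kind)
  write_tsv(pk$peaks[, c("peak_id", "sequence", "center_offset",
                         "differential")],
            sprintf("results/data/peaks_%s.tsv", kind))
  write_tsv(pk$truth, sprintf("results/data/truth_peaks_%s.tsv", kind))
  message(kind, " peaks: ", nrow(pk$peaks), " total, ",
          sum(pk$truth$planted & pk$truth$differential),
          " differential peaks carry a planted site")
}
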