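#!/usr/bin/env Rscript
# Stage 2: scan the simulated transcriptome for seed matches and perfect/
# imperfect centered sites of the pulled-down miRNA, tabulate counts and
# densities per region, and check the scan against the planted truth.

suppressPackageStartupMessages(library(censite))

tx <- read_region_table("results/data/regions.tsv",
                        read_fasta("results/data/transcripts.fa"))
mir_seqs <- read_fasta("results/data/mirnas.fa")
mirnas <- mirna_set(names(mir_seqs), unname(mir_seqs))

sites <- scan_sites(mirnas, tx)
write_tsv(sites, "results/sites.tsv")
write_sites_bed(sites, "results/sites.bed")
message("found ", nrow(sites), " merged sites:")
print(table(sites$site_class, sites$region))

truth <- read_tsv("results/data/truth_sites.tsv")
key_s <- paste(sites$transcript_id, sites$site_class, sites$start, sites$end)
key_t <- paste(truth$transcript_id, truth$site_class, truth$start, truth$end)
message(sum(key_t %in% key_s), " of ", nrow(truth),
        " planted sites recovered at their exact class and position")

counts <- site_count_table(sites, tx, mirnas$mirna_id[1])
write_tsv(counts, "results/site_counts.tsv")
message("count table: ", nrow(counts), " transcript rows, ",
        sum(grepl("^count_", names(counts))), " covariate columns")
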