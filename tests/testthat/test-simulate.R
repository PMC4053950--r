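# Synthetic-data generator: determinism, construction invariants, exact
# planting, and the linear shift model of the simulated pull-down.

test_that("transcriptome generation is a pure function of the seed", {
  cfg <- sim_config(seed = 5, n_transcripts = 60)
  a <- generate_transcriptome(cfg)
  b <- generate_transcriptome(cfg)
  expect_identical(a$transcripts, b$transcripts)
  expect_identical(a$mirnas, b$mirnas)
  expect_identical(a$truth, b$truth)
  d <- generate_transcriptome(sim_config(seed = 6, n_transcripts = 60))
  expect_false(identical(a$transcripts$sequence, d$transcripts$sequence))
})

test_that("region lengths partition each transcript and composition is on target", {
  cfg <- sim_config(seed = 15, n_transcripts = 150)
  sim <- generate_transcriptome(cfg)
  tx <- sim$transcripts
  expect_true(all(tx$utr5_end >= cfg$region_min["UTR5"]))
  expect_true(all(tx$cds_end - tx$utr5_end >= cfg$region_min["CDS"]))
  expect_true(all(tx$length - tx$cds_end >= cfg$region_min["UTR3"]))
  expect_true(all(nchar(tx$sequence) == tx$length))
  # pooled base frequencies within 3 sd of the binomial expectation
  bases <- table(strsplit(paste(tx$sequence, collapse = ""), "")[[1]])
  n <- sum(bases)
  for (b in names(cfg$base_freq)) {
    p <- cfg$base_freq[[b]]
    expect_lt(abs(bases[[b]] / n - p), 3 * sqrt(p * (1 - p) / n) + 0.003)
  }
  # one canonical transcript per gene, the longest
  by_gene <- split(seq_len(nrow(tx)), tx$gene_id)
  for (idx in by_gene[1:20]) {
    can <- idx[tx$is_canonical[idx]]
    expect_length(can, 1L)
    expect_equal(tx$length[can], max(tx$length[idx]))
  }
})

test_that("planting writes a site of exactly the requested class", {
  set.seed(25)
  m <- mirna_set("mir", rand_rna(22))
  for (cl in SITE_CLASSES) {
    for (i in 1:8) {
      tx <- transcript_set("t", "g", rand_rna(500), 100, 350)
      res <- plant_site(tx, m, cl, "UTR3")
      kind <- if (grepl("SEED", cl)) "seed" else "centered"
      hits <- scan_sites(m, res$transcript, kinds = kind)
      hit <- hits[hits$start == res$site$start, ]
      expect_equal(hit$site_class, cl)
      expect_equal(hit$end, res$site$end)
      expect_equal(hit$region, "UTR3")
    }
  }
  # region shorter than the site
  short <- transcript_set("s", "g", rand_rna(100), 45, 92)  # 8-nt 3'UTR
  expect_error(plant_site(short, m, "CEN_GU_1MM", "UTR3"), "plant")
})

test_that("planted GU and mismatch bookkeeping matches the window evaluation", {
  set.seed(26)
  m <- mirna_set("mir", rand_rna(22))
  for (i in 1:20) {
    tx <- transcript_set("t", "g", rand_rna(400), 0, 100)
    cl <- sample(c("CEN_GU_0MM", "CEN_GU_1MM", "CEN_WC_1MM"), 1)
    res <- plant_site(tx, m, cl, "UTR3")
    site_seq <- substr(res$transcript$sequence, res$site$start + 1,
                       res$site$end)
    win <- substr(m$sequence, res$site$mirna_window_start,
                  res$site$mirna_window_start + 10)
    mw <- match_window(win, site_seq)
    expect_equal(mw$n_gu, res$site$n_gu)
    expect_equal(mw$n_mm, res$site$n_mm)
    if (res$site$n_mm == 1)
      expect_equal(mw$mm_positions, res$site$mm_window_position)
  }
})

test_that("every generator truth record is recovered by the scanner", {
  cfg <- sim_config(seed = 35, n_transcripts = 250)
  sim <- generate_transcriptome(cfg)
  hits <- scan_sites(sim$mirnas, sim$transcripts)
  key_s <- paste(hits$transcript_id, hits$mirna_id, hits$site_class,
                 hits$start, hits$end)
  key_t <- paste(sim$truth$transcript_id, sim$truth$mirna_id,
                 sim$truth$site_class, sim$truth$start, sim$truth$end)
  expect_true(all(key_t %in% key_s))
  # scanner regions agree with the planted regions
  mt <- match(key_t, key_s)
  expect_identical(hits$region[mt], sim$truth$region)
})

test_that("the simulated pull-down shift is linear in scanned site counts", {
  cfg <- sim_config(seed = 45, n_transcripts = 200)
  sim <- generate_transcriptome(cfg)
  pd <- simulate_pulldown(sim)
  expect_equal(nrow(pd$truth), nrow(sim$transcripts))
  expect_identical(pd$truth$true_status, pd$truth$delta > 0)

  # adding one 3'UTR seed-site count raises the deterministic shift by its
  # coefficient
  counts2 <- pd$counts
  i <- 7L
  counts2$count_SEED_8MER_UTR3[i] <- counts2$count_SEED_8MER_UTR3[i] + 1L
  eta1 <- censite:::.linear_site_effect(pd$counts, cfg$beta0, cfg$beta)
  eta2 <- censite:::.linear_site_effect(counts2, cfg$beta0, cfg$beta)
  expect_equal(eta2[i] - eta1[i], cfg$beta["SEED_8MER", "UTR3"])
  expect_equal(eta2[-i], eta1[-i])

  # detection p-values exercise the filter: some probes are undetected
  em <- pd$em
  kept <- detection_filter(em, alpha = cfg$detection_alpha)
  expect_lt(nrow(kept$intensities), nrow(em$intensities))
  expect_gt(nrow(kept$intensities), 0.8 * nrow(em$intensities))
})

test_that("status simulation from the logistic model tracks the linear predictor", {
  cfg <- sim_config(seed = 55, n_transcripts = 400)
  sim <- generate_transcriptome(cfg)
  tab <- site_count_table(scan_sites(sim$mirnas, sim$transcripts),
                          sim$transcripts, sim$mirnas$mirna_id[1])
  beta <- matrix(0, 7, 3, dimnames = list(SITE_CLASSES, REGIONS))
  beta["SEED_8MER", "UTR3"] <- 2
  set.seed(56)
  st <- simulate_enrichment_status(tab, -1, beta)
  expect_equal(st$eta, -1 + 2 * tab$count_SEED_8MER_UTR3)
  expect_gt(mean(st$status[st$eta > 0]), mean(st$status[st$eta < 0]))
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_rep = 1), "n_rep")
  pr <- censite:::.default_planting_rates()
  pr[1, 1] <- -0.1
  expect_error(sim_config(planting_rates = pr), "planting_rates")
  expect_error(sim_config(base_freq = c(A = 0.5, C = 0.5, G = 0.2, U = 0.2)),
               "base_freq")
})
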