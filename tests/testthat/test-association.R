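# Exact 2x2 tests, the logistic site model, pseudo r-squared, KS shift
# tests and shared-target comparisons.

test_that("upper-tail exact test matches hypergeometric enumeration", {
  r <- fisher_exact_upper(matrix(c(5, 0, 0, 5), 2, byrow = TRUE))
  expect_equal(r$p, 1 / 252, tolerance = 1e-12)
  expect_true(r$corrected)

  r2 <- fisher_exact_upper(c(1, 1, 1, 1))
  expect_equal(r2$p, 5 / 6, tolerance = 1e-12)
  expect_equal(r2$odds_ratio, 1)
  expect_false(r2$corrected)

  r3 <- fisher_exact_upper(c(0, 3, 4, 2))
  expect_equal(r3$p, 1)

  expect_error(fisher_exact_upper(c(-1, 2, 3, 4)), "non-negative")
  expect_error(fisher_exact_upper(c(0, 0, 3, 4)), "zero margin")

  set.seed(8)
  for (i in 1:50) {
    tab <- rpois(4, 6) + c(1, 0, 0, 1)
    if (any(c(tab[1] + tab[2], tab[3] + tab[4],
              tab[1] + tab[3], tab[2] + tab[4]) == 0)) next
    got <- fisher_exact_upper(tab)
    expect_equal(got$p, oracle_hyper_upper(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-12)
    ft <- stats::fisher.test(matrix(tab, 2, byrow = TRUE),
                             alternative = "greater")
    expect_equal(got$p, ft$p.value, tolerance = 1e-9)
  }
})

test_that("the Woolf interval brackets the sample odds ratio", {
  r <- fisher_exact_upper(c(20, 10, 8, 25))
  expect_equal(r$odds_ratio, 20 * 25 / (10 * 8))
  expect_lt(r$ci_low, r$odds_ratio)
  expect_gt(r$ci_high, r$odds_ratio)
})

test_that("site-type enrichment recovers the planted direction and exclusivity filter", {
  cfg <- sim_config(seed = 51, n_transcripts = 600)
  sim <- generate_transcriptome(cfg)
  hits <- scan_sites(sim$mirnas, sim$transcripts)
  tab <- site_count_table(hits, sim$transcripts, sim$mirnas$mirna_id[1])
  # targets = transcripts whose weighted site burden is positive
  delta <- local({
    b <- cfg$beta
    e <- rep(cfg$beta0, nrow(tab))
    for (cl in SITE_CLASSES) for (rg in REGIONS)
      e <- e + b[cl, rg] * tab[[paste0("count_", cl, "_", rg)]]
    e
  })
  targets <- tab$transcript_id[delta > 0]
  bg <- tab$transcript_id
  for (cl in c("SEED_8MER", "CEN_GU_1MM")) {
    res <- site_type_enrichment(targets, bg, tab, cl)
    expect_gt(res$odds_ratio, 1)
  }
  # exclusive filtering removes multi-class transcripts from the table
  res_ex <- site_type_enrichment(targets, bg, tab, "SEED_8MER",
                                 exclusive = TRUE)
  n_multi <- sum(censite:::.n_classes_present(tab) > 1L)
  expect_equal(res_ex$n, nrow(tab) - n_multi)
})

test_that("intercept-only logistic fit matches the closed form, gradient vanishes", {
  set.seed(61)
  tx <- transcript_set(sprintf("t%03d", 1:80), sprintf("g%03d", 1:80),
                       vapply(1:80, function(i) rand_rna(60), character(1)),
                       0, 30)
  tab <- site_count_table(censite:::.empty_sites(), tx, "m")
  status <- runif(80) < 0.3
  fit <- fit_logistic_sites(status, tab, mode = "count")
  expect_equal(fit$coefficients$estimate[1],
               qlogis(mean(status)), tolerance = 1e-8)
  expect_lt(fit$grad_max, 1e-6)
  expect_equal(fit$r2$nagelkerke, 0, tolerance = 1e-10)
})

test_that("logistic fit recovers planted coefficients and flags separation", {
  set.seed(62)
  cfg <- sim_config(seed = 63, n_transcripts = 1500)
  sim <- generate_transcriptome(cfg)
  hits <- scan_sites(sim$mirnas, sim$transcripts)
  tab <- site_count_table(hits, sim$transcripts, sim$mirnas$mirna_id[1])
  beta <- matrix(0, 7, 3, dimnames = list(SITE_CLASSES, REGIONS))
  beta["SEED_8MER", "UTR3"] <- 1.0
  beta["CEN_GU_1MM", "UTR3"] <- 0.5
  st <- simulate_enrichment_status(tab, -1, beta)
  fit <- fit_logistic_sites(st$status, tab, mode = "count",
                            regions = "UTR3")
  co <- fit$coefficients
  est <- co$estimate[co$term == "count_SEED_8MER_UTR3"]
  se <- co$se[co$term == "count_SEED_8MER_UTR3"]
  expect_lt(abs(est - 1.0), 3 * se)
  expect_true(fit$converged)
  expect_gt(fit$L1, fit$L0)

  # perfectly separating covariate -> error naming it
  tab2 <- tab[1:400, ]
  sep_status <- tab2$count_SEED_8MER_UTR3 > 0
  expect_error(fit_logistic_sites(sep_status, tab2, mode = "count",
                                  classes = "SEED_8MER", regions = "UTR3"),
               "separation")
})

test_that("canonical-only fitting keeps one transcript per gene", {
  cfg <- sim_config(seed = 64, n_transcripts = 300, isoform_rate = 0.5)
  sim <- generate_transcriptome(cfg)
  tab <- site_count_table(scan_sites(sim$mirnas, sim$transcripts),
                          sim$transcripts, sim$mirnas$mirna_id[1])
  set.seed(65)
  st <- simulate_enrichment_status(tab, -1, cfg$beta)
  fit <- fit_logistic_sites(st$status, tab, canonical_only = TRUE)
  expect_equal(fit$n, length(unique(sim$transcripts$gene_id)))
})

test_that("pseudo r-squared follows the Cox-Snell/Nagelkerke formulas", {
  expect_equal(nagelkerke_r2(-10, -10, 50)$nagelkerke, 0)
  expect_equal(nagelkerke_r2(-30, 0, 100)$nagelkerke, 1)
  set.seed(66)
  for (i in 1:30) {
    n <- sample(20:500, 1)
    L0 <- -runif(1, 5, n / 3)
    L1 <- L0 + runif(1, 0, 5)
    got <- nagelkerke_r2(L0, L1, n)
    cs <- 1 - exp(2 * (L0 - L1) / n)
    expect_equal(got$cox_snell, cs, tolerance = 1e-12)
    expect_equal(got$nagelkerke, cs / (1 - exp(2 * L0 / n)),
                 tolerance = 1e-12)
    expect_true(got$nagelkerke >= 0 && got$nagelkerke <= 1)
  }
  expect_error(nagelkerke_r2(-5, -6, 10), "L1")
})

test_that("KS shift test is one-sided in the enrichment direction", {
  x <- c(1, 2, 3, 4)
  expect_equal(ks_shift_test(x, x)$D, 0)
  expect_equal(ks_shift_test(x, x)$p, 1)
  set.seed(67)
  base <- rnorm(200)
  up <- ks_shift_test(base + 1, base)
  expect_lt(up$p, 1e-6)
  down <- ks_shift_test(base - 1, base)
  expect_gt(down$p, 0.5)
  expect_error(ks_shift_test(1, c(1, 2)), ">= 2")

  # null p-values roughly uniform over replicates
  ps <- replicate(200, ks_shift_test(rnorm(40), rnorm(40))$p)
  expect_gt(mean(ps > 0.5), 0.3)
})

test_that("external-set enrichment spans concordance to the null", {
  set.seed(68)
  universe <- sprintf("t%04d", 1:800)
  targets <- sample(universe, 150)
  perfect <- external_set_enrichment(targets, targets, universe)
  expect_lt(perfect$p, 1e-12)
  expect_gt(perfect$odds_ratio, 50)

  ors <- replicate(25, {
    ext <- sample(universe, 200)
    external_set_enrichment(targets, ext, universe)$odds_ratio
  })
  expect_gt(mean(ors), 0.75)
  expect_lt(mean(ors), 1.3)
  expect_error(external_set_enrichment(targets, targets, character(0)),
               "empty universe")
})

test_that("set overlap returns exact Venn counts", {
  expect_equal(set_overlap(c("a", "b"), c("c")),
               list(a_only = 2L, b_only = 1L, both = 0L))
  expect_equal(set_overlap(c("a", "b"), c("a", "b")),
               list(a_only = 0L, b_only = 0L, both = 2L))
  set.seed(69)
  for (i in 1:10) {
    a <- sample(letters, sample(5:20, 1))
    b <- sample(letters, sample(5:20, 1))
    ov <- set_overlap(a, b)
    expect_equal(ov$both, sum(unique(a) %in% b))
    expect_equal(ov$a_only + ov$both, length(unique(a)))
  }
})

test_that("shared isomiR targets show the planted centered-site excess", {
  set.seed(70)
  cfg <- sim_config(seed = 71, n_transcripts = 1200)
  sim <- generate_transcriptome(cfg)
  hits <- scan_sites(sim$mirnas, sim$transcripts)
  tab <- site_count_table(hits, sim$transcripts, sim$mirnas$mirna_id[1])
  has_cen <- rowSums(sapply(SITE_CLASSES[4:7], function(cl)
    censite:::.has_class(tab, cl))) > 0
  ids <- tab$transcript_id
  # shared targets drawn preferentially from centered-site carriers,
  # unique targets preferentially from non-carriers
  shared <- c(sample(ids[has_cen], 200), sample(ids[!has_cen], 10))
  pool_c <- setdiff(ids[has_cen], shared)
  pool_n <- setdiff(ids[!has_cen], shared)
  a_only <- c(sample(pool_c, 100), sample(pool_n, 70))
  pool_c <- setdiff(pool_c, a_only)
  pool_n <- setdiff(pool_n, a_only)
  b_only <- c(sample(pool_c, 100), sample(pool_n, 70))
  res <- isomir_shared_site_test(c(shared, a_only), c(shared, b_only), tab,
                                 SITE_CLASSES[4:7], exclusive = FALSE)
  expect_gt(res$shared_vs_a_only$odds_ratio, 1)
  expect_gt(res$shared_vs_b_only$odds_ratio, 1)
  expect_lt(res$shared_vs_a_only$p, 0.05)

  expect_error(isomir_shared_site_test(c("x", "y"), c("x", "y"), tab,
                                       "CEN_WC_0MM"),
               "unique target sets")
})
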