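# Detection filtering, quantile normalisation, the moderated t statistic
# and its limits, BH FDR, and target-set assembly.

make_em <- function(n = 50, n_rep = 3, delta = rep(0, n), noise = 0.3,
                    seed = 1) {
  set.seed(seed)
  simulate_expression(stats::setNames(delta, sprintf("p%03d", seq_len(n))),
                      n_rep = n_rep, noise_sd = noise)
}

test_that("detection filter keeps probes detected in every control sample", {
  em <- make_em(n = 4)
  dp <- matrix(0.005, 4, 6, dimnames = dimnames(em$intensities))
  dp[2, 5] <- 0.02   # one control above threshold
  dp[3, 1] <- 0.9    # pull-down sample does not matter
  em$detection_p <- dp
  kept <- detection_filter(em, alpha = 0.01)
  expect_equal(rownames(kept$intensities), c("p001", "p003", "p004"))
  expect_equal(rownames(detection_filter(em, alpha = 1.0)$intensities),
               rownames(em$intensities))
  em2 <- em
  em2$groups <- rep("PULLDOWN", 6)
  expect_error(detection_filter(em2), "no control samples")
  em3 <- make_em(n = 4)
  expect_error(detection_filter(em3), "no detection p-values")
})

test_that("quantile normalisation equalises sorted columns and matches limma", {
  skip_if_not_installed("limma")
  set.seed(5)
  x <- matrix(2^rnorm(600, 8, 1.5), 100, 6,
              dimnames = list(sprintf("p%03d", 1:100),
                              sprintf("s%d", 1:6)))
  em <- expression_matrix(x, rep(c("PULLDOWN", "CONTROL"), each = 3))
  nm <- normalize_expression(em)
  sorted <- apply(nm$intensities, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
  ref <- limma::normalizeQuantiles(log2(x))
  expect_equal(unname(nm$intensities), unname(as.matrix(ref)),
               tolerance = 1e-10)

  # already-identical samples are a fixed point
  y <- matrix(rep(2^seq(1, 5, length.out = 20), 4), 20, 4,
              dimnames = list(sprintf("q%02d", 1:20), sprintf("s%d", 1:4)))
  em2 <- expression_matrix(y, rep(c("PULLDOWN", "CONTROL"), each = 2))
  expect_equal(normalize_expression(em2)$intensities, log2(y))

  y[3, 2] <- -1
  em3 <- expression_matrix(y, rep(c("PULLDOWN", "CONTROL"), each = 2))
  expect_error(normalize_expression(em3), "q03.*s2")
})

test_that("moderated t is centred under equality and recovers ordinary t at d0 = 0", {
  em <- make_em(n = 200, seed = 7)
  x <- em$intensities
  x[1, 1:3] <- x[1, 4:6]   # pull-down identical to control
  em$intensities <- log2(x)
  em$log2_scale <- TRUE
  res <- moderated_t_enrichment(em)
  expect_equal(res$t[1], 0)
  expect_equal(res$p[1], 0.5)
  expect_true(all(res$q >= res$p))
  expect_identical(res$enriched, res$q <= 0.05)

  res0 <- moderated_t_enrichment(em, d0 = 0, s02 = 0)
  ref <- apply(log2(2^em$intensities), 1, function(v)
    stats::t.test(v[1:3], v[4:6], var.equal = TRUE,
                  alternative = "greater")$p.value)
  expect_equal(res0$p, unname(ref), tolerance = 1e-10)

  # d0 -> Inf: z statistic with fixed variance s02
  resInf <- moderated_t_enrichment(em, d0 = Inf, s02 = 0.25)
  lfc <- res0$logFC
  zref <- lfc / sqrt(0.25 * (2 / 3))
  expect_equal(resInf$t, zref, tolerance = 1e-10)
  expect_equal(resInf$p, stats::pnorm(zref, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("fitted variance prior agrees with the limma empirical Bayes fit", {
  skip_if_not_installed("limma")
  em <- make_em(n = 500, seed = 21, noise = 0.4)
  nm <- normalize_expression(em)
  res <- moderated_t_enrichment(nm)
  design <- cbind(1, rep(c(1, 0), each = 3))
  fit <- limma::lmFit(nm$intensities, design)
  eb <- limma::eBayes(fit)
  expect_equal(attr(res, "d0"), eb$df.prior, tolerance = 0.05)
  expect_equal(attr(res, "s02"), eb$s2.prior, tolerance = 0.05)
  # one-sided p from limma's two-sided moderated t
  p1 <- ifelse(eb$t[, 2] > 0, eb$p.value[, 2] / 2, 1 - eb$p.value[, 2] / 2)
  expect_equal(res$p, unname(p1), tolerance = 1e-6)
})

test_that("null moderated-t p-values are approximately uniform", {
  set.seed(33)
  em <- simulate_expression(stats::setNames(rep(0, 1000),
                                            sprintf("p%04d", 1:1000)),
                            n_rep = 3, noise_sd = 0.35)
  em$intensities <- log2(em$intensities)
  em$log2_scale <- TRUE
  res <- moderated_t_enrichment(em)
  ks <- suppressWarnings(stats::ks.test(res$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("raising a probe's pull-down intensities never lowers its t", {
  em <- make_em(n = 60, seed = 9)
  em$intensities <- log2(em$intensities)
  em$log2_scale <- TRUE
  base <- moderated_t_enrichment(em)
  for (bump in c(0.1, 0.5, 1.5)) {
    em2 <- em
    em2$intensities[10, em2$groups == "PULLDOWN"] <-
      em2$intensities[10, em2$groups == "PULLDOWN"] + bump
    expect_gte(moderated_t_enrichment(em2)$t[10], base$t[10])
  }
})

test_that("moderated t input contracts are enforced", {
  em <- make_em(n = 5)
  em$intensities <- log2(em$intensities)
  em$log2_scale <- TRUE
  em$intensities <- em$intensities[, c(1, 4)]
  em$groups <- c("PULLDOWN", "CONTROL")
  expect_error(moderated_t_enrichment(em), ">= 2 replicates")

  cm <- matrix(4, 5, 4, dimnames = list(sprintf("p%d", 1:5),
                                        sprintf("s%d", 1:4)))
  emz <- expression_matrix(cm, rep(c("PULLDOWN", "CONTROL"), each = 2),
                           log2_scale = TRUE)
  expect_error(moderated_t_enrichment(emz), "zero within-group variance")
})

test_that("BH adjustment matches the literal step-up", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))
  expect_equal(bh_fdr(rep(0.2, 7)), rep(0.2, 7))
  set.seed(15)
  for (i in 1:20) {
    p <- runif(sample(3:200, 1))^sample(1:3, 1)
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
  }
  expect_error(bh_fdr(numeric(0)), "empty")
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("target calling maps enriched probes and excludes ambiguous transcripts", {
  res <- data.frame(probe_id = c("a", "b", "c"),
                    logFC = c(2, 1, 0), t = c(5, 3, 0), df = 10,
                    p = c(1e-4, 1e-3, 0.5), q = c(0.01, 0.04, 0.6),
                    enriched = c(TRUE, TRUE, FALSE),
                    stringsAsFactors = FALSE)
  pm <- data.frame(probe_id = c("a", "a", "b", "c"),
                   transcript_id = c("T1", "T2", "T3", "T3"),
                   stringsAsFactors = FALSE)
  ts <- call_targets(res, pm, fdr = 0.05)
  expect_setequal(ts$targets, c("T1", "T2"))
  expect_equal(ts$ambiguous, "T3")   # also hit by the flat probe c
  ts2 <- call_targets(res, pm, fdr = 0.05, exclude_ambiguous = FALSE)
  expect_setequal(ts2$targets, c("T1", "T2", "T3"))
  ts3 <- call_targets(res, pm, fdr = 0.02)
  expect_setequal(ts3$targets, c("T1", "T2"))  # q = 0.04 probe not enriched
  expect_false("T3" %in% ts3$targets)

  expect_message(call_targets(res, pm[pm$probe_id != "a", ], fdr = 0.05),
                 "missing from the probe map")
  expect_error(call_targets(res[0, ], pm), "empty")
})

test_that("enrichment calling is deterministic for identical input", {
  em <- make_em(n = 100, seed = 77, delta = c(rep(1, 10), rep(0, 90)))
  nm <- normalize_expression(em)
  r1 <- moderated_t_enrichment(nm)
  r2 <- moderated_t_enrichment(nm)
  expect_identical(r1, r2)
})
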