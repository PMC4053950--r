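# Seed and centered site scanning: pairing rules, window enumeration,
# classification, merging, and agreement with the per-position oracle.

test_that("base-pair classification follows Watson-Crick and wobble rules", {
  expect_equal(pair_class("G", "C"), "WC")
  expect_equal(pair_class("A", "U"), "WC")
  expect_equal(pair_class("G", "U"), "GU")
  expect_equal(pair_class("U", "G"), "GU")
  expect_equal(pair_class("A", "G"), "MM")
  expect_equal(pair_class(c("A", "G"), c("U", "U")), c("WC", "GU"))
  expect_error(pair_class("X", "A"), "invalid RNA base")
})

test_that("centered windows are the contained 11-mers at positions 3-5", {
  w <- centered_windows(rand_rna(22))
  expect_equal(w$window_start, c(3L, 4L, 5L))
  expect_true(all(nchar(w$window_seq) == 11L))

  s15 <- rand_rna(15)
  w15 <- centered_windows(s15)
  expect_equal(w15$window_start, c(3L, 4L, 5L))
  expect_equal(w15$window_seq[3], substr(s15, 5, 15))

  expect_warning(w14 <- centered_windows(rand_rna(14)), "only 2 of 3")
  expect_equal(w14$window_start, c(3L, 4L))
  expect_error(suppressWarnings(centered_windows(rand_rna(12))), "too short")
})

test_that("window evaluation pairs antiparallel and counts all 11 pairs", {
  set.seed(101)
  w <- rand_rna(11)
  m <- match_window(w, rna_revcomp(w))
  expect_equal(m$n_wc, 11L)
  expect_equal(m$n_gu, 0L)
  expect_equal(m$n_mm, 0L)

  # one U -> G substitution opposite a window U gives a single wobble
  w2 <- "AAAAAUAAAAA"
  site <- strsplit(rna_revcomp(w2), "")[[1]]
  site[12 - 6] <- "G"  # opposite window position 6 (the U)
  m2 <- match_window(w2, paste(site, collapse = ""))
  expect_equal(m2$n_gu, 1L)
  expect_equal(m2$n_mm, 0L)
  expect_equal(m2$gu_positions, 6L)

  expect_error(match_window("ACGU", rand_rna(11)), "11 nt")

  for (i in 1:300) {
    ww <- rand_rna(11); ss <- rand_rna(11)
    got <- match_window(ww, ss)
    want <- oracle_match_counts(ww, ss)
    expect_identical(got[c("n_wc", "n_gu", "n_mm")],
                     want[c("n_wc", "n_gu", "n_mm")])
    expect_equal(got$mm_positions, want$mm_positions)
  }
})

test_that("centered classification applies budgets, interior rule and precedence", {
  mk <- function(n_gu, n_mm, mm_pos = integer(0), gu_pos = integer(0)) {
    list(n_wc = 11L - n_gu - n_mm, n_gu = n_gu, n_mm = n_mm,
         mm_positions = mm_pos, gu_positions = gu_pos)
  }
  expect_equal(classify_centered(mk(0L, 0L)), "CEN_WC_0MM")
  expect_equal(classify_centered(mk(2L, 0L, gu_pos = c(3L, 7L))), "CEN_GU_0MM")
  expect_equal(classify_centered(mk(0L, 1L, 5L)), "CEN_WC_1MM")
  expect_equal(classify_centered(mk(2L, 1L, 5L, c(3L, 7L))), "CEN_GU_1MM")
  expect_true(is.na(classify_centered(mk(0L, 2L, c(4L, 6L)))))
  expect_true(is.na(classify_centered(mk(0L, 1L, 11L))))   # terminal mismatch
  expect_true(is.na(classify_centered(mk(0L, 1L, 1L))))
  expect_equal(classify_centered(mk(0L, 1L, 11L), interior_only = FALSE),
               "CEN_WC_1MM")
  # wobbles become mismatches when GU pairing is off
  expect_true(is.na(classify_centered(mk(2L, 0L, gu_pos = c(3L, 7L)),
                                      allow_gu = FALSE)))
  expect_equal(classify_centered(mk(1L, 0L, gu_pos = 5L), allow_gu = FALSE),
               "CEN_WC_1MM")
  expect_true(is.na(classify_centered(mk(3L, 0L, gu_pos = c(3L, 5L, 7L)),
                                      max_gu = 2L)))
})

test_that("planted centered sites are found at the planted offset and class", {
  set.seed(202)
  m <- mirna_set("m", rand_rna(22))
  win <- substr(m$sequence, 3, 13)
  perfect <- rna_revcomp(win)
  seq <- paste0(rand_rna(80), perfect, rand_rna(80))
  tx <- transcript_set("t", "g", seq, 10, 120)
  hits <- scan_centered(m, tx)
  planted <- hits[hits$start == 80, ]
  expect_equal(nrow(planted), 1L)
  expect_equal(planted$site_class, "CEN_WC_0MM")
  expect_equal(planted$end, 91)

  # one interior mismatch -> CEN_WC_1MM
  sc <- strsplit(perfect, "")[[1]]
  j <- 6  # window position 6 -> site position 12-6
  b <- substr(win, j, j)
  comp <- c(A = "U", C = "G", G = "C", U = "A")[b]
  wob <- c(G = "U", U = "G")[b]
  sc[12 - j] <- setdiff(c("A", "C", "G", "U"), c(comp, wob))[1]
  seq2 <- paste0(rand_rna(40), paste(sc, collapse = ""), rand_rna(40))
  tx2 <- transcript_set("t2", "g2", seq2, 0, 0)
  hits2 <- scan_centered(m, tx2)
  planted2 <- hits2[hits2$start == 40, ]
  expect_equal(planted2$site_class, "CEN_WC_1MM")
  expect_equal(planted2$n_mm, 1L)

  # transcript shorter than a site -> empty
  short <- transcript_set("s", "gs", rand_rna(9), 0, 0)
  expect_equal(nrow(scan_centered(m, short)), 0L)
})

test_that("seed classes follow the TargetScanS definitions", {
  set.seed(303)
  m <- mirna_set("m", rand_rna(22))
  rc7 <- rna_revcomp(substr(m$sequence, 2, 8))

  tx8 <- transcript_set("t8", "g", paste0(rand_rna(50), rc7, "A", rand_rna(50)),
                        0, 0)
  h8 <- scan_seed(m, tx8)
  expect_true(any(h8$site_class == "SEED_8MER" & h8$start == 50 & h8$end == 58))

  nonA <- "C"
  txm8 <- transcript_set("tm8", "g",
                         paste0(rand_rna(50), rc7, nonA, rand_rna(50)), 0, 0)
  hm8 <- scan_seed(m, txm8)
  expect_true(any(hm8$site_class == "SEED_7MER_M8" & hm8$start == 50 &
                  hm8$end == 57))
})

test_that("scanner equals the per-position oracle on random sequences", {
  set.seed(404)
  param_sets <- list(scan_params(),
                     scan_params(allow_gu = FALSE),
                     scan_params(max_mm = 0L),
                     scan_params(interior_only = FALSE),
                     scan_params(max_gu = 2L))
  for (i in 1:12) {
    mseq <- rand_rna(22)
    tseq <- rand_rna(400)
    m <- mirna_set("m", mseq)
    tx <- transcript_set("t", "g", tseq, 100, 300)
    ps <- param_sets[[(i - 1L) %% length(param_sets) + 1L]]
    expect_scan_equals_oracle(
      scan_centered(m, tx, ps),
      oracle_scan_centered(mseq, tseq, allow_gu = ps$allow_gu,
                           max_mm = ps$max_mm,
                           interior_only = ps$interior_only,
                           max_gu = ps$max_gu))
    expect_scan_equals_oracle(scan_seed(m, tx), oracle_scan_seed(mseq, tseq))
  }
})

test_that("precedence keeps loci exclusive and never downgrades a perfect site", {
  set.seed(505)
  for (i in 1:20) {
    m <- mirna_set("m", rand_rna(22))
    win <- substr(m$sequence, 4, 14)
    seq <- paste0(rand_rna(60), rna_revcomp(win), rand_rna(60))
    tx <- transcript_set("t", "g", seq, 0, 0)
    hits <- scan_centered(m, tx)
    ov <- hits[hits$start < 71 & hits$end > 60, ]
    expect_equal(nrow(ov), 1L)
    expect_equal(ov$site_class, "CEN_WC_0MM")
  }
  # no two reported sites of one family overlap
  m <- mirna_set("m", rand_rna(22))
  tx <- transcript_set("t", "g", rand_rna(3000), 500, 2500)
  hits <- scan_centered(m, tx)
  if (nrow(hits) > 1L) {
    o <- order(hits$start)
    expect_true(all(hits$start[o][-1L] >= hits$end[o][-nrow(hits)]))
  }
})

test_that("each centered window's reverse complement is a perfect site", {
  set.seed(606)
  m <- mirna_set("m", rand_rna(22))
  wins <- centered_windows(m$sequence)
  for (k in seq_len(nrow(wins))) {
    tx <- transcript_set("t", "g",
                         paste0(rand_rna(30), rna_revcomp(wins$window_seq[k]),
                                rand_rna(30)), 0, 0)
    hits <- scan_centered(m, tx)
    expect_true(any(hits$site_class == "CEN_WC_0MM"))
  }
})
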