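# Independent oracles: per-position enumeration scanners built on string
# operations (the package scanner works on integer-encoded concatenated
# sequences in C++), a literal hypergeometric tail enumeration, and a
# literal Benjamini-Hochberg step-up.

rand_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

# dinucleotide (miRNA base, mRNA base) -> pair type, by explicit listing
ORACLE_PAIR <- local({
  v <- rep("MM", 16)
  names(v) <- as.vector(outer(c("A", "C", "G", "U"), c("A", "C", "G", "U"),
                              paste0))
  v[c("AU", "UA", "GC", "CG")] <- "WC"
  v[c("GU", "UG")] <- "GU"
  v
})

# chain-merge with explicit loop: overlapping hits collapse to the most
# stringent class; ties -> smallest start, then smallest window start
oracle_merge <- function(hits, precedence) {
  if (is.null(hits) || nrow(hits) == 0L) return(hits)
  hits <- hits[order(hits$start, hits$end, hits$mirna_window_start), ,
               drop = FALSE]
  out <- list()
  best <- hits[1L, , drop = FALSE]
  chain_end <- best$end
  better <- function(h, b) {
    ph <- match(h$site_class, precedence)
    pb <- match(b$site_class, precedence)
    ph < pb || (ph == pb && (h$start < b$start ||
      (h$start == b$start && h$mirna_window_start < b$mirna_window_start)))
  }
  for (i in seq_len(nrow(hits))[-1L]) {
    h <- hits[i, , drop = FALSE]
    if (h$start < chain_end) {
      chain_end <- max(chain_end, h$end)
      if (better(h, best)) best <- h
    } else {
      out[[length(out) + 1L]] <- best
      best <- h
      chain_end <- h$end
    }
  }
  out[[length(out) + 1L]] <- best
  res <- do.call(rbind, out)
  res[order(res$start), , drop = FALSE]
}

oracle_match_counts <- function(window_seq, site_seq) {
  wch <- strsplit(window_seq, "")[[1L]]
  sch <- strsplit(site_seq, "")[[1L]]
  types <- ORACLE_PAIR[paste0(wch, sch[12L - (1:11)])]
  list(n_wc = sum(types == "WC"), n_gu = sum(types == "GU"),
       n_mm = sum(types == "MM"),
       mm_positions = unname(which(types == "MM")),
       gu_positions = unname(which(types == "GU")))
}

oracle_scan_centered <- function(mirna_seq, tx_seq, allow_gu = TRUE,
                                 max_mm = 1, interior_only = TRUE,
                                 max_gu = Inf, merge = TRUE) {
  mch <- strsplit(mirna_seq, "")[[1L]]
  sch <- strsplit(tx_seq, "")[[1L]]
  L <- length(sch)
  rows <- list()
  if (L >= 11) {
    for (w in 3:5) {
      if (w + 10 > length(mch)) next
      wch <- mch[w:(w + 10)]
      for (s in 0:(L - 11)) {
        types <- ORACLE_PAIR[paste0(wch, sch[s + 12L - (1:11)])]
        if (!allow_gu) types[types == "GU"] <- "MM"
        n_mm <- sum(types == "MM")
        if (n_mm > max_mm) next
        n_gu <- sum(types == "GU")
        if (n_gu > max_gu) next
        if (interior_only && any(which(types == "MM") %in% c(1L, 11L))) next
        cls <- if (n_mm == 0 && n_gu == 0) "CEN_WC_0MM"
          else if (n_mm == 0) "CEN_GU_0MM"
          else if (n_gu == 0) "CEN_WC_1MM"
          else "CEN_GU_1MM"
        rows[[length(rows) + 1L]] <- data.frame(
          start = s, end = s + 11L, site_class = cls,
          mirna_window_start = w, stringsAsFactors = FALSE)
      }
    }
  }
  hits <- if (length(rows) > 0L) do.call(rbind, rows) else NULL
  if (merge)
    hits <- oracle_merge(hits, c("CEN_WC_0MM", "CEN_GU_0MM",
                                 "CEN_WC_1MM", "CEN_GU_1MM"))
  hits
}

oracle_scan_seed <- function(mirna_seq, tx_seq, merge = TRUE) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  mch <- strsplit(mirna_seq, "")[[1L]]
  rc7 <- paste(rev(unname(comp[mch[2:8]])), collapse = "")
  rc6 <- paste(rev(unname(comp[mch[2:7]])), collapse = "")
  L <- nchar(tx_seq)
  rows <- list()
  if (L >= 7) {
    seven <- substring(tx_seq, 1:(L - 6), 7:L)
    after <- c(substring(tx_seq, 8:L, 8:L), "")[seq_len(L - 6)]
    for (i in which(seven == rc7)) {
      s <- i - 1L
      if (after[i] == "A") {
        rows[[length(rows) + 1L]] <- data.frame(
          start = s, end = s + 8L, site_class = "SEED_8MER",
          mirna_window_start = 1L, stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          start = s, end = s + 7L, site_class = "SEED_7MER_M8",
          mirna_window_start = 2L, stringsAsFactors = FALSE)
      }
    }
    six <- substring(tx_seq, 1:(L - 5), 6:L)
    for (i in which(six == rc6)) {
      s <- i - 1L
      if (s + 7 > L) next
      if (substring(tx_seq, s + 7, s + 7) != "A") next
      if (s >= 1 && substring(tx_seq, s, s) == unname(comp[mch[8L]])) next
      rows[[length(rows) + 1L]] <- data.frame(
        start = s, end = s + 7L, site_class = "SEED_7MER_A1",
        mirna_window_start = 1L, stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(rows) > 0L) do.call(rbind, rows) else NULL
  if (merge)
    hits <- oracle_merge(hits, c("SEED_8MER", "SEED_7MER_M8",
                                 "SEED_7MER_A1"))
  hits
}

# compare scanner output with oracle output for one transcript/miRNA
expect_scan_equals_oracle <- function(hits, oracle) {
  key <- function(df) {
    if (is.null(df) || nrow(df) == 0L) return(character(0))
    sort(paste(df$site_class, df$start, df$end, df$mirna_window_start))
  }
  expect_identical(key(hits), key(oracle))
}

# exact hypergeometric upper tail by explicit enumeration over the support
oracle_hyper_upper <- function(w, x, y, z) {
  N <- w + x + y + z
  K <- w + y       # site carriers
  n1 <- w + x      # targets drawn
  ks <- max(0, n1 - (N - K)):min(n1, K)
  pr <- exp(lchoose(K, ks) + lchoose(N - K, n1 - ks) - lchoose(N, n1))
  sum(pr[ks >= w])
}

# literal BH step-up: q_(i) = min_{j >= i} p_(j) * m / j, capped at 1
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  qs <- vapply(seq_len(m), function(i) min(1, min(sorted[i:m] * m / (i:m))),
               numeric(1))
  q <- numeric(m)
  q[o] <- qs
  q
}
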