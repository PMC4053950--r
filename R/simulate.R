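## Synthetic-data generator: transcriptomes with planted sites of every
## class, pull-down expression matrices whose log-intensity shift is
## linear in the scanned site counts, and AGO-peak sets whose planted
## sites cluster near peak centers.  Every stage is a pure function of
## (config, seed); per-stage seeds are derived from the master seed so
## stages are reproducible independently of execution order.

.derive_seed <- function(seed, label) {
  u <- utf8ToInt(label)
  h <- sum(u * seq_along(u)) %% 104729
  as.integer((as.numeric(seed) %% 1048573 * 1009 + h * 7919 + 17) %% 2147483629)
}

.default_planting_rates <- function() {
  m <- matrix(0, length(SITE_CLASSES), length(REGIONS),
              dimnames = list(SITE_CLASSES, REGIONS))
  m[, "UTR5"] <- 0.02
  m[, "CDS"] <- 0.06
  m[, "UTR3"] <- 0.12
  m
}

.default_beta <- function() {
  m <- matrix(0, length(SITE_CLASSES), length(REGIONS),
              dimnames = list(SITE_CLASSES, REGIONS))
  m["SEED_8MER", ]    <- c(0.20, 0.70, 1.30)
  m["SEED_7MER_M8", ] <- c(0.20, 0.60, 1.10)
  m["SEED_7MER_A1", ] <- c(0.15, 0.50, 0.90)
  m["CEN_WC_0MM", ]   <- c(0.15, 0.50, 0.90)
  m["CEN_GU_0MM", ]   <- c(0.10, 0.45, 0.80)
  m["CEN_WC_1MM", ]   <- c(0.10, 0.40, 0.70)
  m["CEN_GU_1MM", ]   <- c(0.10, 0.35, 0.60)
  m
}

#' Simulation configuration
#'
#' Defaults describe the emulated study conditions: a transcriptome of
#' 5,000 transcripts with log-normal region lengths (median 5'UTR 150 nt,
#' CDS 1,200 nt, 3'UTR 800 nt), i.i.d. uniform base composition, sites of
#' all seven classes planted mostly in the 3'UTR and CDS, pull-down
#' log2-intensity shifts linear in site counts (intercept -2, set so that
#' roughly a fifth of transcripts are true targets, as in a pull-down;
#' per-site
#' effects strongest for seeds in the 3'UTR) over 3+3 replicates with
#' 0.35 log2 replicate noise, and 4,000 AGO peaks of which 10% are
#' differential with sites planted at Gaussian offsets (sd 8 nt) from the
#' peak center.
#'
#' @param seed Master RNG seed.
#' @param n_transcripts Number of transcripts.
#' @param isoform_rate Fraction of transcripts belonging to two-isoform
#'   genes (pairs share a gene id).
#' @param region_meanlog,region_sdlog Named numeric vectors (UTR5, CDS,
#'   UTR3) of log-normal length parameters.
#' @param region_min Named integer vector of minimum region lengths.
#' @param base_freq Base composition (A, C, G, U).
#' @param n_mirnas,mirna_length Number and length of simulated miRNAs.
#' @param planting_rates 7x3 matrix (class x region) of expected planted
#'   sites per transcript (Poisson).
#' @param beta0,beta Intercept and 7x3 matrix of per-site log2-shift
#'   effects.
#' @param n_rep Replicates per group.
#' @param noise_sd Replicate noise sd (log2).
#' @param baseline_mean,baseline_sd Baseline log2-intensity distribution.
#' @param probe_effect_sd Sd of a per-probe random shift added to the
#'   deterministic pull-down shift (default 0 keeps truth unambiguous).
#' @param undetected_fraction Fraction of probes simulated as undetected
#'   in controls (to exercise the detection filter).
#' @param detection_alpha,fdr Detection and FDR thresholds.
#' @param n_peaks,differential_fraction Peak count and differential share.
#' @param half_window Peak scan half-window (nt).
#' @param peak_offset_sd Sd of planted-site offsets in differential peaks.
#' @param peak_site_prob Probability a differential peak gets a planted
#'   site.
#' @param peak_background_rate Probability an unchanged peak gets a site
#'   at a uniform offset.
#' @return List of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L,
                       n_transcripts = 5000L,
                       isoform_rate = 0.2,
                       region_meanlog = c(UTR5 = log(150), CDS = log(1200),
                                          UTR3 = log(800)),
                       region_sdlog = c(UTR5 = 0.5, CDS = 0.45, UTR3 = 0.6),
                       region_min = c(UTR5 = 15L, CDS = 90L, UTR3 = 40L),
                       base_freq = c(A = 0.25, C = 0.25, G = 0.25, U = 0.25),
                       n_mirnas = 1L, mirna_length = 22L,
                       planting_rates = .default_planting_rates(),
                       beta0 = -2, beta = .default_beta(),
                       n_rep = 3L, noise_sd = 0.35,
                       baseline_mean = 8, baseline_sd = 1.2,
                       probe_effect_sd = 0,
                       undetected_fraction = 0.05,
                       detection_alpha = 0.01, fdr = 0.05,
                       n_peaks = 4000L, differential_fraction = 0.1,
                       half_window = 200L, peak_offset_sd = 8,
                       peak_site_prob = 0.95,
                       peak_background_rate = 0.03) {
  stopifnot(all(planting_rates >= 0), n_rep >= 2L, n_transcripts >= 1L,
            all(base_freq >= 0), abs(sum(base_freq) - 1) < 1e-8)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

## ---- site-sequence construction -----------------------------------------

## Wobble partner on the mRNA side for a miRNA base (G pairs U, U pairs G),
## NA when the base cannot wobble.
.wobble_partner <- c(A = NA, C = NA, G = "U", U = "G")
.wc_partner <- c(A = "U", C = "G", G = "C", U = "A")

## Build the mRNA-side fragment realising a site of exactly the requested
## class.  Returns fragment (5'->3'), the site interval within the
## fragment (0-based), window start, and the gu/mm bookkeeping.
.make_site_fragment <- function(mirna_seq, site_class) {
  m <- strsplit(mirna_seq, "")[[1L]]
  if (site_class %in% c("SEED_8MER", "SEED_7MER_M8", "SEED_7MER_A1")) {
    rc7 <- rev(.wc_partner[m[2:8]])
    if (site_class == "SEED_8MER") {
      frag <- c(rc7, "A")
      return(list(fragment = paste(frag, collapse = ""), site_start = 0L,
                  site_end = 8L, window_start = 1L, n_gu = 0L, n_mm = 0L,
                  mm_window_position = NA_integer_))
    }
    if (site_class == "SEED_7MER_M8") {
      frag <- c(rc7, sample(c("C", "G", "U"), 1L))  # non-A opposite pos 1
      return(list(fragment = paste(frag, collapse = ""), site_start = 0L,
                  site_end = 7L, window_start = 2L, n_gu = 0L, n_mm = 0L,
                  mm_window_position = NA_integer_))
    }
    rc6 <- rev(.wc_partner[m[2:7]])
    no_m8 <- sample(setdiff(RNA_BASES, .wc_partner[m[8L]]), 1L)
    frag <- c(no_m8, rc6, "A")
    return(list(fragment = paste(frag, collapse = ""), site_start = 1L,
                site_end = 8L, window_start = 1L, n_gu = 0L, n_mm = 0L,
                mm_window_position = NA_integer_))
  }

  ## centered classes: pick a window whose composition supports the class
  w_start <- sample(3:5, 1L)
  w <- m[w_start:(w_start + 10L)]
  site <- rev(.wc_partner[w])  # site position 12-j pairs window position j
  n_gu <- 0L; n_mm <- 0L; mm_pos <- NA_integer_
  gu_j <- integer(0)
  ## guard bases flanking the site: a planted duplex for window w also
  ## lines up with window w+d at site offset -d (and w-d at +d), needing
  ## only the flanking bases to pair; guards forced to mismatch the
  ## relevant miRNA positions kill those shifted alignments so the merged
  ## call keeps the planted coordinates.
  mm_base <- function(b) {
    bad <- c(.wc_partner[b], .wobble_partner[b])
    ok <- setdiff(RNA_BASES, bad[!is.na(bad)])
    ok[sample.int(length(ok), 1L)]
  }
  d_left <- seq_len(5L - w_start)
  d_left <- d_left[w_start + d_left + 10L <= length(m)]
  left_guards <- rev(vapply(d_left, function(d)
    mm_base(m[w_start + 10L + d]), character(1)))   # outermost first
  d_right <- seq_len(w_start - 3L)
  d_right <- d_right[w_start - d_right + 10L <= length(m)]
  right_guards <- vapply(d_right, function(d)
    mm_base(m[w_start - d]), character(1))
  if (site_class %in% c("CEN_GU_0MM", "CEN_GU_1MM")) {
    elig <- which(w %in% c("G", "U"))
    if (length(elig) == 0L) stop("window has no wobble-capable base")
    k <- min(2L, length(elig))
    if (k > 1L) k <- sample.int(k, 1L)
    gu_j <- sort(elig[sample.int(length(elig), k)])
    site[12L - gu_j] <- .wobble_partner[w[gu_j]]
    n_gu <- k
  }
  if (site_class %in% c("CEN_WC_1MM", "CEN_GU_1MM")) {
    interior <- setdiff(2:10, gu_j)
    mm_pos <- interior[sample.int(length(interior), 1L)]
    b <- w[mm_pos]
    disallowed <- c(.wc_partner[b], .wobble_partner[b])
    site[12L - mm_pos] <- sample(setdiff(RNA_BASES,
                                         disallowed[!is.na(disallowed)]), 1L)
    n_mm <- 1L
  }
  frag <- c(left_guards, site, right_guards)
  list(fragment = paste(frag, collapse = ""),
       site_start = length(left_guards),
       site_end = length(left_guards) + 11L, window_start = w_start,
       n_gu = n_gu, n_mm = n_mm, mm_window_position = mm_pos)
}

#' Plant a binding site of an exact class into a transcript
#'
#' Writes a site of exactly the requested class at a uniformly chosen
#' position inside the requested region, then verifies with the scanner
#' that the realised (merged) call at that locus has the planted class
#' and coordinates, re-rolling the position and site sequence otherwise.
#'
#' @param transcript One-row \code{\link{transcript_set}}.
#' @param mirna One-row \code{\link{mirna_set}}.
#' @param site_class One of \code{\link{SITE_CLASSES}}.
#' @param region "UTR5", "CDS" or "UTR3".
#' @param retries Bounded retries (default 25).
#' @return List with \code{transcript} (modified set) and \code{site}
#'   (one-row record: site_class, region, start, end, window_start,
#'   n_gu, n_mm, mm_window_position).
#' @export
plant_site <- function(transcript, mirna, site_class, region, retries = 25L) {
  stopifnot(inherits(transcript, "transcript_set"), nrow(transcript) == 1L,
            inherits(mirna, "mirna_set"), nrow(mirna) == 1L,
            site_class %in% SITE_CLASSES, region %in% REGIONS)
  res <- .plant_in_seq(transcript$sequence, transcript$utr5_end,
                       transcript$cds_end, mirna$sequence, site_class,
                       region, occupied = NULL, retries = retries,
                       verify = TRUE)
  if (is.null(res))
    stop("could not plant a ", site_class, " site in the ", region,
         " (region too short or retries exhausted)", call. = FALSE)
  transcript$sequence <- res$sequence
  list(transcript = transcript,
       site = data.frame(transcript_id = transcript$transcript_id,
                         mirna_id = mirna$mirna_id, site_class = site_class,
                         region = region, start = res$start, end = res$end,
                         mirna_window_start = res$window_start,
                         n_gu = res$n_gu, n_mm = res$n_mm,
                         mm_window_position = res$mm_window_position,
                         stringsAsFactors = FALSE))
}

## Core planting on a bare sequence.  `occupied` is a 2-column matrix of
## 0-based half-open intervals already used (with the caller's buffer).
## Returns NULL if the region cannot host the site or retries run out.
.plant_in_seq <- function(seq, utr5_end, cds_end, mirna_seq, site_class,
                          region, occupied = NULL, retries = 25L,
                          verify = TRUE) {
  len <- nchar(seq)
  bounds <- switch(region, UTR5 = c(0L, utr5_end),
                   CDS = c(utr5_end, cds_end), UTR3 = c(cds_end, len))
  for (try in seq_len(retries)) {
    fr <- .make_site_fragment(mirna_seq, site_class)
    flen <- nchar(fr$fragment)
    if (bounds[2L] - bounds[1L] < flen) return(NULL)
    fstart <- bounds[1L] + sample.int(bounds[2L] - bounds[1L] - flen + 1L,
                                      1L) - 1L
    s_start <- fstart + fr$site_start
    s_end <- fstart + fr$site_end
    if (!is.null(occupied) && nrow(occupied) > 0L &&
        any(fstart < occupied[, 2L] + 11L &
            fstart + flen > occupied[, 1L] - 11L)) next
    cand <- seq
    substr(cand, fstart + 1L, fstart + flen) <- fr$fragment
    if (verify && !.verify_planted(cand, mirna_seq, site_class,
                                   s_start, s_end)) next
    return(list(sequence = cand, start = s_start, end = s_end,
                fragment_start = fstart, fragment_end = fstart + flen,
                window_start = fr$window_start, n_gu = fr$n_gu,
                n_mm = fr$n_mm, mm_window_position = fr$mm_window_position))
  }
  NULL
}

## local scanner check: the merged call overlapping the planted interval
## must be exactly (start, end, class).  A window of +/-33 nt captures any
## overlap chain that could absorb the planted site.
.verify_planted <- function(seq, mirna_seq, site_class, s_start, s_end) {
  len <- nchar(seq)
  a <- max(0L, s_start - 33L)
  b <- min(len, s_end + 33L)
  sub <- substr(seq, a + 1L, b)
  kind <- if (grepl("^SEED", site_class)) "seed" else "centered"
  tx <- transcript_set("v", "v", sub, 0L, 0L)
  mi <- suppressWarnings(mirna_set("m", mirna_seq))
  hits <- scan_sites(mi, tx, kinds = kind)
  ov <- hits[hits$end > s_start - a & hits$start < s_end - a, , drop = FALSE]
  nrow(ov) == 1L && ov$start == s_start - a && ov$end == s_end - a &&
    ov$site_class == site_class
}

## ---- transcriptome generation -------------------------------------------

#' Generate a synthetic transcriptome with planted sites
#'
#' Samples gene/isoform structure, log-normal region lengths and i.i.d.
#' base composition, simulates the miRNAs, and plants sites of every
#' class at the configured per-(class, region) Poisson rates.  After
#' planting, the whole transcriptome is re-scanned and any transcript
#' whose planted sites are not recovered exactly (a rare accident of
#' background context) is regenerated, so the returned truth table is
#' consistent with the scanner by construction.
#'
#' @param config A \code{\link{sim_config}}.
#' @return List of class \code{sim_transcriptome}: \code{transcripts},
#'   \code{mirnas}, \code{truth} (planted-site records), \code{config}.
#' @export
generate_transcriptome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.derive_seed(config$seed, "transcriptome"))
  n <- config$n_transcripts

  n_pair_tx <- 2L * floor(config$isoform_rate * n / 2)
  gene_id <- character(n)
  if (n_pair_tx > 0L)
    gene_id[seq_len(n_pair_tx)] <- rep(sprintf("G%05d", seq_len(n_pair_tx / 2L)),
                                       each = 2L)
  n_single <- n - n_pair_tx
  if (n_single > 0L)
    gene_id[(n_pair_tx + 1L):n] <- sprintf("G%05d",
                                           n_pair_tx / 2L + seq_len(n_single))
  transcript_id <- sprintf("T%05d", seq_len(n))

  rl <- vapply(REGIONS, function(r) {
    pmax(config$region_min[[r]],
         round(stats::rlnorm(n, config$region_meanlog[[r]],
                             config$region_sdlog[[r]])))
  }, numeric(n))
  rl <- matrix(as.integer(rl), nrow = n,
               dimnames = list(NULL, REGIONS))
  lens <- rowSums(rl)

  gen_seq <- function(total) {
    paste(sample(RNA_BASES, total, replace = TRUE, prob = config$base_freq),
          collapse = "")
  }
  big <- gen_seq(sum(lens))
  ends <- cumsum(lens)
  seqs <- substring(big, c(1, ends[-n] + 1), ends)

  mir_seqs <- vapply(seq_len(config$n_mirnas), function(i)
    paste(sample(RNA_BASES, config$mirna_length, replace = TRUE),
          collapse = ""), character(1))
  mirnas <- mirna_set(sprintf("mir%02d", seq_len(config$n_mirnas)), mir_seqs)

  ## planting plan: Poisson events per (transcript, miRNA, class, region)
  plan <- list()
  for (mi in seq_len(nrow(mirnas))) {
    for (cl in SITE_CLASSES) {
      for (rg in REGIONS) {
        rate <- config$planting_rates[cl, rg]
        if (rate <= 0) next
        k <- stats::rpois(n, rate)
        idx <- rep(which(k > 0L), times = k[k > 0L])
        if (length(idx) > 0L)
          plan[[length(plan) + 1L]] <- data.frame(
            tx = idx, mi = mi, site_class = cl, region = rg,
            stringsAsFactors = FALSE)
      }
    }
  }
  plan <- if (length(plan) > 0L) do.call(rbind, plan) else
    data.frame(tx = integer(0), mi = integer(0),
               site_class = character(0), region = character(0))
  plan <- plan[order(plan$tx, plan$mi, plan$site_class, plan$region), ,
               drop = FALSE]
  plan_by_tx <- split(seq_len(nrow(plan)), plan$tx)

  plant_tx <- function(i, seq_i) {
    ev <- plan_by_tx[[as.character(i)]]
    occ <- matrix(integer(0), ncol = 2L)
    rec <- vector("list", length(ev))
    for (k in seq_along(ev)) {
      e <- ev[k]
      res <- .plant_in_seq(seq_i, rl[i, "UTR5"], rl[i, "UTR5"] + rl[i, "CDS"],
                           mirnas$sequence[plan$mi[e]], plan$site_class[e],
                           plan$region[e], occupied = occ, retries = 25L,
                           verify = FALSE)
      if (is.null(res)) next  # region too short or crowded; skip event
      seq_i <- res$sequence
      occ <- rbind(occ, c(res$fragment_start, res$fragment_end))
      rec[[k]] <- list(transcript_id[i], mirnas$mirna_id[plan$mi[e]],
                       plan$site_class[e], plan$region[e], res$start,
                       res$end, res$window_start, res$n_gu, res$n_mm,
                       res$mm_window_position)
    }
    rec <- rec[!vapply(rec, is.null, logical(1))]
    list(seq = seq_i, rec = if (length(rec) > 0L) rec else NULL)
  }

  truth <- vector("list", n)
  todo <- unique(plan$tx)
  for (i in todo) {
    p <- plant_tx(i, seqs[i])
    seqs[i] <- p$seq
    truth[[i]] <- p$rec
  }

  build_set <- function() {
    transcript_set(transcript_id, gene_id, seqs, rl[, "UTR5"],
                   rl[, "UTR5"] + rl[, "CDS"], validate = FALSE)
  }
  transcripts <- build_set()

  flatten_truth <- function(truth) {
    rows <- unlist(truth, recursive = FALSE, use.names = FALSE)
    if (length(rows) == 0L) return(NULL)
    cols <- lapply(seq_len(10L), function(j)
      unlist(lapply(rows, `[[`, j), use.names = FALSE))
    names(cols) <- c("transcript_id", "mirna_id", "site_class", "region",
                     "start", "end", "mirna_window_start", "n_gu", "n_mm",
                     "mm_window_position")
    as.data.frame(cols, stringsAsFactors = FALSE)
  }

  ## verify planted sites against the full merged scan; regenerate the
  ## few transcripts where background context absorbed a planted site
  for (round in seq_len(5L)) {
    tdf <- flatten_truth(truth)
    if (is.null(tdf) || nrow(tdf) == 0L) break
    scanned <- scan_sites(mirnas, transcripts)
    key_s <- paste(scanned$transcript_id, scanned$mirna_id,
                   scanned$site_class, scanned$start, scanned$end)
    key_t <- paste(tdf$transcript_id, tdf$mirna_id, tdf$site_class,
                   tdf$start, tdf$end)
    bad_tx <- unique(tdf$transcript_id[!(key_t %in% key_s)])
    if (length(bad_tx) == 0L) break
    if (round == 5L)
      stop("planted-site verification failed to converge", call. = FALSE)
    for (id in bad_tx) {
      i <- match(id, transcript_id)
      seqs[i] <- gen_seq(lens[i])
      p <- plant_tx(i, seqs[i])
      seqs[i] <- p$seq
      truth[[i]] <- p$rec
    }
    transcripts <- build_set()
  }

  truth <- flatten_truth(truth)
  if (is.null(truth)) truth <- .empty_sites()
  rownames(truth) <- NULL
  structure(list(transcripts = transcripts, mirnas = mirnas, truth = truth,
                 config = config), class = "sim_transcriptome")
}

## ---- expression simulation ----------------------------------------------

#' Build a replicate expression matrix from per-probe true shifts
#'
#' Control replicates are baseline + noise; pull-down replicates add the
#' per-probe shift \code{delta}.  Intensities are returned on the linear
#' scale (2^log2).  RNG state is the caller's.
#'
#' @param delta Named numeric vector of true log2 shifts (names = probes).
#' @param n_rep Replicates per group.
#' @param noise_sd Replicate noise sd (log2).
#' @param baseline_mean,baseline_sd Baseline log2-intensity parameters.
#' @param detection_p Optional detection p-value matrix to attach.
#' @return An \code{\link{expression_matrix}} (linear scale).
#' @export
simulate_expression <- function(delta, n_rep = 3L, noise_sd = 0.35,
                                baseline_mean = 8, baseline_sd = 1.2,
                                detection_p = NULL) {
  n <- length(delta)
  probes <- names(delta)
  if (is.null(probes)) probes <- sprintf("p%05d", seq_len(n))
  base <- stats::rnorm(n, baseline_mean, baseline_sd)
  ctrl <- base + matrix(stats::rnorm(n * n_rep, 0, noise_sd), n, n_rep)
  pull <- base + delta + matrix(stats::rnorm(n * n_rep, 0, noise_sd), n, n_rep)
  x <- 2^cbind(pull, ctrl)
  dimnames(x) <- list(probes, c(sprintf("PD%d", seq_len(n_rep)),
                                sprintf("CT%d", seq_len(n_rep))))
  expression_matrix(x, c(rep("PULLDOWN", n_rep), rep("CONTROL", n_rep)),
                    detection_p = detection_p, log2_scale = FALSE)
}

#' Simulate a biotin pull-down experiment over a planted transcriptome
#'
#' One probe per transcript (identity probe map).  The pull-down shift of
#' probe i is \code{delta_i = beta0 + sum_ab beta_ab * x_ab,i (+ eps_i)}
#' with \code{x} the SCANNED site counts of the pulled-down miRNA (so the
#' truth accounts for accidental background sites, not only planted
#' ones); the true enrichment status is \code{deterministic part > 0}.
#' Detection p-values are emitted, with a configured fraction of probes
#' made undetectable in controls to exercise the detection filter.
#'
#' @param sim A \code{\link{generate_transcriptome}} result.
#' @param mirna_id Which simulated miRNA is pulled down (default first).
#' @param counts Optional precomputed \code{\link{site_count_table}}.
#' @return List of class \code{sim_pulldown}: \code{em} (linear-scale
#'   \code{expression_matrix} with detection p), \code{probe_map},
#'   \code{truth} (probe_id, transcript_id, delta, true_status),
#'   \code{counts}, \code{mirna_id}.
#' @export
simulate_pulldown <- function(sim, mirna_id = sim$mirnas$mirna_id[1L],
                              counts = NULL) {
  stopifnot(inherits(sim, "sim_transcriptome"))
  config <- sim$config
  if (is.null(counts)) {
    matches <- scan_sites(sim$mirnas[sim$mirnas$mirna_id == mirna_id, ],
                          sim$transcripts)
    counts <- site_count_table(matches, sim$transcripts,
                               mirna_ids = mirna_id)
  }
  if (!all(counts$transcript_id == sim$transcripts$transcript_id))
    stop("count table does not match the transcriptome", call. = FALSE)
  set.seed(.derive_seed(config$seed, paste0("pulldown_", mirna_id)))

  eta <- .linear_site_effect(counts, config$beta0, config$beta)
  n <- nrow(counts)
  eps <- if (config$probe_effect_sd > 0)
    stats::rnorm(n, 0, config$probe_effect_sd) else numeric(n)
  delta <- eta + eps
  probes <- paste0("p_", counts$transcript_id)
  names(delta) <- probes

  n_samp <- 2L * config$n_rep
  dp <- matrix(stats::runif(n * n_samp, 0, config$detection_alpha / 2),
               n, n_samp)
  n_undet <- round(config$undetected_fraction * n)
  if (n_undet > 0L) {
    undet <- sample.int(n, n_undet)
    dp[undet, ] <- stats::runif(n_undet * n_samp, 0.2, 0.9)
  }
  em <- simulate_expression(delta, n_rep = config$n_rep,
                            noise_sd = config$noise_sd,
                            baseline_mean = config$baseline_mean,
                            baseline_sd = config$baseline_sd,
                            detection_p = NULL)
  dimnames(dp) <- dimnames(em$intensities)
  em$detection_p <- dp

  structure(list(
    em = em,
    probe_map = data.frame(probe_id = probes,
                           transcript_id = counts$transcript_id,
                           stringsAsFactors = FALSE),
    truth = data.frame(probe_id = probes,
                       transcript_id = counts$transcript_id,
                       delta = eta, true_status = eta > 0,
                       stringsAsFactors = FALSE),
    counts = counts, mirna_id = mirna_id), class = "sim_pulldown")
}

## beta0 + sum over (class, region) of beta * count
.linear_site_effect <- function(counts, beta0, beta) {
  eta <- rep(beta0, nrow(counts))
  for (cl in SITE_CLASSES) {
    for (rg in REGIONS) {
      b <- beta[cl, rg]
      if (b != 0) eta <- eta + b * counts[[paste0("count_", cl, "_", rg)]]
    }
  }
  eta
}

#' Draw Bernoulli enrichment status from the logistic model
#'
#' For regression parameter-recovery studies: status is drawn from
#' \code{logit(p) = beta0 + sum beta_ab x_ab} with x the count (or
#' density) covariates of \code{tables}.  RNG state is the caller's.
#'
#' @param tables A \code{\link{site_count_table}}.
#' @param beta0 Intercept.
#' @param beta 7x3 matrix of coefficients (class x region).
#' @param mode "count" or "density" covariates.
#' @return List with \code{status} (logical) and \code{eta} (linear
#'   predictor).
#' @export
simulate_enrichment_status <- function(tables, beta0, beta,
                                       mode = c("count", "density")) {
  mode <- match.arg(mode)
  prefix <- if (mode == "count") "count_" else "dens_"
  eta <- rep(beta0, nrow(tables))
  for (cl in SITE_CLASSES) {
    for (rg in REGIONS) {
      b <- beta[cl, rg]
      if (b != 0) eta <- eta + b * tables[[paste0(prefix, cl, "_", rg)]]
    }
  }
  list(status = stats::runif(nrow(tables)) < stats::plogis(eta), eta = eta)
}

## ---- peak simulation ----------------------------------------------------

#' Simulate an AGO peak set with center-clustered planted sites
#'
#' A configured fraction of peaks is differential; each differential peak
#' receives (with probability \code{peak_site_prob}) a planted site at a
#' Gaussian-distributed signed offset from the peak center, while
#' unchanged peaks receive sites at the background rate at uniform
#' offsets.  Planted sites are verified against a bulk scan and peaks
#' whose site was absorbed by background context are resampled.
#'
#' @param config A \code{\link{sim_config}}.
#' @param mirna One-row \code{\link{mirna_set}}.
#' @param kind Plant seed or centered sites.
#' @param site_classes Classes to sample planted sites from (default: the
#'   classes of \code{kind}).
#' @return List of class \code{sim_peaks}: \code{peaks} (a
#'   \code{\link{peak_set}}), \code{truth} (peak_id, planted, site_class,
#'   offset).
#' @export
simulate_peaks <- function(config, mirna, kind = c("seed", "centered"),
                           site_classes = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(mirna, "mirna_set"),
            nrow(mirna) == 1L)
  kind <- match.arg(kind)
  hw <- as.integer(config$half_window)
  if (config$peak_offset_sd >= hw)
    stop("peak offset sd must be smaller than the half-window", call. = FALSE)
  if (is.null(site_classes))
    site_classes <- if (kind == "seed") SITE_CLASSES[1:3] else SITE_CLASSES[4:7]
  set.seed(.derive_seed(config$seed, paste0("peaks_", kind)))

  n <- config$n_peaks
  len <- 2L * hw + 1L
  center <- hw
  n_diff <- round(config$differential_fraction * n)
  differential <- c(rep(TRUE, n_diff), rep(FALSE, n - n_diff))
  peak_id <- sprintf("pk%05d", seq_len(n))

  rand_seq <- function(k) paste(sample(RNA_BASES, k * len, replace = TRUE,
                                       prob = config$base_freq),
                                collapse = "")
  seqs <- substring(rand_seq(n), (seq_len(n) - 1L) * len + 1L,
                    seq_len(n) * len)

  want_plant <- ifelse(differential,
                       stats::runif(n) < config$peak_site_prob,
                       stats::runif(n) < config$peak_background_rate)
  planted_class <- rep(NA_character_, n)
  planted_offset <- rep(NA_integer_, n)

  plant_peak <- function(s, is_diff) {
    for (try in seq_len(25L)) {
      cl <- sample(site_classes, 1L)
      fr <- .make_site_fragment(mirna$sequence, cl)
      w <- fr$site_end - fr$site_start
      off <- if (is_diff) {
        as.integer(round(stats::rnorm(1L, 0, config$peak_offset_sd)))
      } else {
        sample.int(2L * (hw - 10L) + 1L, 1L) - (hw - 10L) - 1L
      }
      s_start <- center + off - (w - 1L) %/% 2L
      fstart <- s_start - fr$site_start
      flen <- nchar(fr$fragment)
      if (fstart < 0L || fstart + flen > len) next
      cand <- s
      substr(cand, fstart + 1L, fstart + flen) <- fr$fragment
      if (!.verify_planted(cand, mirna$sequence, cl, s_start, s_start + w))
        next
      return(list(seq = cand, class = cl, offset = off))
    }
    NULL
  }

  for (i in which(want_plant)) {
    res <- plant_peak(seqs[i], differential[i])
    if (is.null(res)) next
    seqs[i] <- res$seq
    planted_class[i] <- res$class
    planted_offset[i] <- res$offset
  }

  peaks <- peak_set(peak_id, seqs, center_offset = center,
                    differential = differential)
  truth <- data.frame(peak_id = peak_id, differential = differential,
                      planted = !is.na(planted_class),
                      site_class = planted_class, offset = planted_offset,
                      stringsAsFactors = FALSE)
  structure(list(peaks = peaks, truth = truth, kind = kind,
                 half_window = hw), class = "sim_peaks")
}
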