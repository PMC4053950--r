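## Seed and centered site scanners.
##
## A centered site is an 11-nt antiparallel duplex between the mRNA and the
## central region of the miRNA, with the miRNA-side window starting at
## position 3, 4 or 5 (1-based from the 5' end).  Window position j pairs
## with site position 12-j (both read 5'->3').  Sites are classified as
## CEN_WC_0MM / CEN_GU_0MM / CEN_WC_1MM / CEN_GU_1MM by whether they use
## G:U wobble and whether they carry one internal mismatch.
##
## The bulk scanner concatenates all transcripts with an N separator,
## encodes once, and evaluates all offsets with 11 shifted vectorised
## lookups per window; N poisons any window that crosses a boundary.

#' Scanner parameters
#'
#' @param allow_gu Treat G:U wobble pairs as pairing-competent in centered
#'   sites (default TRUE); when FALSE they count as mismatches.
#' @param max_mm Maximum number of mismatches in a centered site (default 1).
#' @param interior_only Restrict mismatches to interior window positions
#'   2..10 of the 11-mer; a mismatch at position 1 or 11 disqualifies the
#'   site (default TRUE).
#' @param max_gu Maximum number of wobble pairs (default unlimited).
#' @param merge_overlaps Merge overlapping hits at a locus into a single
#'   site keeping the most stringent class (default TRUE); FALSE returns
#'   raw per-window hits.
#' @return A list of class \code{scan_params}.
#' @export
scan_params <- function(allow_gu = TRUE, max_mm = 1L, interior_only = TRUE,
                        max_gu = Inf, merge_overlaps = TRUE) {
  stopifnot(max_mm >= 0L, max_gu >= 0)
  structure(list(allow_gu = isTRUE(allow_gu), max_mm = as.integer(max_mm),
                 interior_only = isTRUE(interior_only), max_gu = max_gu,
                 merge_overlaps = isTRUE(merge_overlaps)),
            class = "scan_params")
}

#' Centered windows of a miRNA
#'
#' Returns the 11-mer miRNA windows starting at positions 3, 4 and 5
#' (1-based), restricted to those fully contained in the miRNA.  A miRNA
#' of length >= 15 carries all three; lengths 13-14 yield a partial set
#' with a warning; below 13 no window fits and an error is raised.
#'
#' @param mirna A miRNA sequence (character scalar) or a one-row
#'   \code{mirna_set}.
#' @return data.frame with columns \code{window_start} (1-based miRNA
#'   position) and \code{window_seq} (11-mer), ascending by start.
#' @export
centered_windows <- function(mirna) {
  seq <- if (inherits(mirna, "mirna_set")) mirna$sequence[1L] else
    normalize_rna(mirna, "miRNA sequence")
  len <- nchar(seq)
  starts <- c(3L, 4L, 5L)
  fits <- starts + 10L <= len
  if (!any(fits))
    stop("miRNA too short for any centered window (need >= 13 nt)",
         call. = FALSE)
  if (!all(fits))
    warning(sprintf("miRNA of length %d: only %d of 3 centered windows fit",
                    len, sum(fits)), call. = FALSE)
  starts <- starts[fits]
  data.frame(window_start = starts,
             window_seq = substring(seq, starts, starts + 10L),
             stringsAsFactors = FALSE)
}

#' Evaluate one 11-mer window against one 11-mer site
#'
#' Pairs antiparallel: window position j (miRNA 5'->3') against site
#' position 12-j (mRNA 5'->3'), classifying each of the 11 pairs as
#' Watson-Crick, G:U wobble or mismatch.
#'
#' @param window_seq 11-mer miRNA window.
#' @param site_seq 11-mer mRNA subsequence, 5'->3'.
#' @return List with \code{n_wc}, \code{n_gu}, \code{n_mm} (summing to 11),
#'   \code{mm_positions} and \code{gu_positions} (1-based window positions).
#' @export
match_window <- function(window_seq, site_seq) {
  if (nchar(window_seq) != 11L || nchar(site_seq) != 11L)
    stop("window and site must both be 11 nt", call. = FALSE)
  w <- .encode_rna(normalize_rna(window_seq, "window"))
  s <- .encode_rna(normalize_rna(site_seq, "site"))
  cls <- .PC[cbind(w, s[12L - seq_len(11L)])]
  list(n_wc = sum(cls == 2L), n_gu = sum(cls == 1L), n_mm = sum(cls == 0L),
       mm_positions = which(cls == 0L), gu_positions = which(cls == 1L))
}

#' Classify a window evaluation into a centered-site class
#'
#' Applies, in order: the mismatch budget (\code{max_mm}), the
#' interior-mismatch rule (no mismatch at window position 1 or 11 when
#' \code{interior_only}), and the wobble budget.  When \code{allow_gu} is
#' FALSE wobble pairs are counted as mismatches.  The returned label is the
#' most stringent applicable class: CEN_WC_0MM > CEN_GU_0MM > CEN_WC_1MM >
#' CEN_GU_1MM (WC classes require zero wobbles).
#'
#' @param m A \code{\link{match_window}} result.
#' @inheritParams scan_params
#' @return A class label, or \code{NA_character_} if the site does not
#'   qualify.
#' @export
classify_centered <- function(m, allow_gu = TRUE, max_mm = 1L,
                              interior_only = TRUE, max_gu = Inf) {
  if (allow_gu) {
    gu <- m$n_gu; mm <- m$n_mm; mm_pos <- m$mm_positions
  } else {
    gu <- 0L; mm <- m$n_mm + m$n_gu
    mm_pos <- sort(c(m$mm_positions, m$gu_positions))
  }
  if (mm > max_mm || gu > max_gu) return(NA_character_)
  if (interior_only && any(mm_pos %in% c(1L, 11L))) return(NA_character_)
  if (mm == 0L) {
    if (gu == 0L) "CEN_WC_0MM" else "CEN_GU_0MM"
  } else {
    if (gu == 0L) "CEN_WC_1MM" else "CEN_GU_1MM"
  }
}

## ---- bulk cores over an encoded (concatenated) sequence ------------------

## centered hits of one 11-mer window against encoded sequence `enc`
## (inner loop in C++).  Returns 0-based starts plus per-hit detail.
.scan_window_enc <- function(enc, wenc, window_start, params) {
  if (length(enc) < 11L) return(NULL)
  max_gu <- if (is.finite(params$max_gu)) params$max_gu else 11
  h <- cpp_scan_centered(enc, wenc, params$max_mm, params$allow_gu,
                         max_gu, params$interior_only)
  if (length(h$start) == 0L) return(NULL)
  cls <- ifelse(h$n_mm == 0L,
                ifelse(h$n_gu == 0L, "CEN_WC_0MM", "CEN_GU_0MM"),
                ifelse(h$n_gu == 0L, "CEN_WC_1MM", "CEN_GU_1MM"))
  data.frame(start = h$start, end = h$start + 11L, site_class = cls,
             mirna_window_start = window_start, n_gu = h$n_gu,
             n_mm = h$n_mm,
             mm_window_position = ifelse(h$mm_pos == 0L, NA_integer_,
                                         h$mm_pos),
             stringsAsFactors = FALSE)
}

## seed hits (8mer / 7mer-m8 / 7mer-A1, exact Watson-Crick only).
.scan_seed_enc <- function(enc, menc) {
  if (length(enc) < 7L) return(NULL)
  rc7 <- .COMP[menc[8:2]]          # site-side 7-mer opposite miRNA 2..8
  rc6 <- .COMP[menc[7:2]]          # site-side 6-mer opposite miRNA 2..7
  h <- cpp_scan_seed(enc, rc7, rc6, .COMP[menc[8L]])
  if (length(h$start) == 0L) return(NULL)
  cls <- c("SEED_8MER", "SEED_7MER_M8", "SEED_7MER_A1")[h$type]
  width <- c(8L, 7L, 7L)[h$type]
  data.frame(start = h$start, end = h$start + width, site_class = cls,
             mirna_window_start = c(1L, 2L, 1L)[h$type], n_gu = 0L,
             n_mm = 0L, mm_window_position = NA_integer_,
             stringsAsFactors = FALSE)
}

## merge overlapping hits of one miRNA within one site family: chains of
## mutually overlapping intervals collapse to the most stringent member;
## ties break on smallest start, then smallest window start.  Operates on
## global (concatenated) coordinates -- the N separator guarantees chains
## never span transcripts.
.merge_hits <- function(df) {
  if (is.null(df) || nrow(df) <= 1L) return(df)
  o <- order(df$start, df$end)
  df <- df[o, , drop = FALSE]
  n <- nrow(df)
  cm <- cummax(df$end)
  grp <- cumsum(c(TRUE, df$start[-1L] >= cm[-n]))
  rank <- .CLASS_RANK[df$site_class]
  sel <- order(grp, rank, df$start, df$mirna_window_start)
  pick <- sel[!duplicated(grp[sel])]
  df[sort(pick), , drop = FALSE]
}

## ---- public scanning API -------------------------------------------------

#' Scan transcripts for miRNA binding sites
#'
#' Evaluates every transcript position against every centered window
#' (kind "centered") and/or the seed definitions (kind "seed") of every
#' miRNA.  Overlapping hits of one miRNA within one family are merged to a
#' single site keeping the most stringent class (8mer > 7mer-m8 > 7mer-A1;
#' CEN_WC_0MM > CEN_GU_0MM > CEN_WC_1MM > CEN_GU_1MM), ties resolved by
#' smallest start.  Transcript coordinates are 0-based half-open; each site
#' is assigned to the region (5'UTR/CDS/3'UTR) containing its midpoint.
#'
#' @param mirnas A \code{\link{mirna_set}}.
#' @param transcripts A \code{\link{transcript_set}}.
#' @param params A \code{\link{scan_params}} object.
#' @param kinds Character subset of \code{c("seed", "centered")}.
#' @return data.frame of site matches with columns transcript_id, mirna_id,
#'   site_class, start, end, region, mirna_window_start, n_gu, n_mm,
#'   mm_window_position.
#' @export
scan_sites <- function(mirnas, transcripts, params = scan_params(),
                       kinds = c("seed", "centered")) {
  stopifnot(inherits(mirnas, "mirna_set"),
            inherits(transcripts, "transcript_set"))
  kinds <- match.arg(kinds, several.ok = TRUE)
  nt <- nrow(transcripts)
  if (nt == 0L) return(.empty_sites())
  big <- paste(transcripts$sequence, collapse = "N")
  enc <- .encode_rna(big)
  tx_start0 <- cumsum(c(0L, transcripts$length[-nt] + 1L))  # 0-based global

  out <- vector("list", nrow(mirnas))
  for (i in seq_len(nrow(mirnas))) {
    mi <- mirnas[i, ]
    menc <- .encode_rna(mi$sequence)
    fam <- list()
    if ("centered" %in% kinds) {
      wins <- centered_windows(mi$sequence)
      cen <- lapply(seq_len(nrow(wins)), function(k)
        .scan_window_enc(enc, .encode_rna(wins$window_seq[k]),
                         wins$window_start[k], params))
      cen <- do.call(rbind, cen[!vapply(cen, is.null, logical(1))])
      fam$centered <- cen
    }
    if ("seed" %in% kinds) fam$seed <- .scan_seed_enc(enc, menc)

    pieces <- lapply(fam, function(df) {
      if (is.null(df) || nrow(df) == 0L) return(NULL)
      if (params$merge_overlaps) df <- .merge_hits(df)
      tx <- findInterval(df$start, tx_start0)
      df$transcript_id <- transcripts$transcript_id[tx]
      df$start <- df$start - tx_start0[tx]
      df$end <- df$end - tx_start0[tx]
      df
    })
    df <- do.call(rbind, pieces[!vapply(pieces, is.null, logical(1))])
    if (!is.null(df) && nrow(df) > 0L) {
      df$mirna_id <- mi$mirna_id
      ti <- match(df$transcript_id, transcripts$transcript_id)
      mid <- .site_midpoint(df$start, df$end)
      df$region <- .region_of(mid, transcripts$utr5_end[ti],
                              transcripts$cds_end[ti])
      out[[i]] <- df
    }
  }
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) return(.empty_sites())
  out <- out[order(out$mirna_id, out$transcript_id, out$start), ]
  rownames(out) <- NULL
  out[, c("transcript_id", "mirna_id", "site_class", "start", "end",
          "region", "mirna_window_start", "n_gu", "n_mm",
          "mm_window_position")]
}

.empty_sites <- function() {
  data.frame(transcript_id = character(0), mirna_id = character(0),
             site_class = character(0), start = integer(0), end = integer(0),
             region = character(0), mirna_window_start = integer(0),
             n_gu = integer(0), n_mm = integer(0),
             mm_window_position = integer(0), stringsAsFactors = FALSE)
}

#' @rdname scan_sites
#' @export
scan_centered <- function(mirnas, transcripts, params = scan_params()) {
  scan_sites(mirnas, transcripts, params, kinds = "centered")
}

#' @rdname scan_sites
#' @export
scan_seed <- function(mirnas, transcripts) {
  scan_sites(mirnas, transcripts, kinds = "seed")
}
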