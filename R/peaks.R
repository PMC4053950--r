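## Position of predicted sites relative to AGO-bound peak centers:
## signed offsets of site midpoints, their excess kurtosis (sites mediating
## binding should concentrate at the crosslink peak center), and
## enrichment of site-carrying peaks among differentially detected peaks.

#' Construct a set of AGO peaks
#'
#' @param peak_id Character vector of unique ids.
#' @param sequence RNA sequence context of each peak (>= 11 nt; T
#'   converted to U).
#' @param center_offset 0-based offset of the peak center nucleotide
#'   within the sequence; default is the (lower) midpoint.
#' @param differential Logical: peak detected only in wild type
#'   (miRNA-present) versus unchanged.
#' @return data.frame of class \code{peak_set}.
#' @export
peak_set <- function(peak_id, sequence, center_offset = NULL,
                     differential = FALSE) {
  if (anyDuplicated(peak_id))
    stop("duplicate peak id", call. = FALSE)
  sequence <- normalize_rna(sequence, "peak sequence")
  len <- nchar(sequence)
  if (any(len < 11L))
    stop("peak sequences must be >= 11 nt", call. = FALSE)
  if (is.null(center_offset)) center_offset <- (len - 1L) %/% 2L
  center_offset <- as.integer(center_offset)
  if (any(center_offset < 0L | center_offset >= len))
    stop("peak center must lie within the sequence", call. = FALSE)
  out <- data.frame(peak_id = as.character(peak_id), sequence = sequence,
                    length = len, center_offset = center_offset,
                    differential = rep_len(as.logical(differential),
                                           length(peak_id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("peak_set", "data.frame")
  out
}

#' Signed site offsets from peak centers
#'
#' Scans the window of \code{half_window} nt either side of each peak
#' center for seed or centered sites of a miRNA and records the signed
#' offset of every site midpoint from the center nucleotide (negative =
#' 5' of the center).  Peaks whose sequence does not cover the full
#' window are skipped with a warning.
#'
#' @param peaks A \code{\link{peak_set}}.
#' @param mirna A one-row \code{\link{mirna_set}}.
#' @param kind \code{"seed"} or \code{"centered"}.
#' @param half_window Half-width of the scanned window in nt (default 200).
#' @param params \code{\link{scan_params}} for centered scanning.
#' @return List of class \code{peak_site_profile}: \code{offsets}
#'   (data.frame peak_id/site_class/offset), \code{presence} (named
#'   logical per scanned peak), \code{n_sites}, \code{g2} (excess
#'   kurtosis of the offsets; NA when fewer than 4 offsets or zero
#'   variance), \code{kind}, \code{half_window}.
#' @export
site_offsets <- function(peaks, mirna, kind = c("seed", "centered"),
                         half_window = 200L, params = scan_params()) {
  stopifnot(inherits(peaks, "peak_set"), inherits(mirna, "mirna_set"),
            nrow(mirna) == 1L)
  kind <- match.arg(kind)
  half_window <- as.integer(half_window)
  ok <- peaks$center_offset - half_window >= 0L &
    peaks$center_offset + half_window <= peaks$length - 1L
  if (any(!ok))
    warning(sum(!ok), " peak(s) shorter than the scan window; skipped",
            call. = FALSE)
  pk <- peaks[ok, , drop = FALSE]
  if (nrow(pk) == 0L)
    return(structure(list(offsets = data.frame(peak_id = character(0),
                                               site_class = character(0),
                                               offset = integer(0)),
                          presence = logical(0), n_sites = 0L,
                          g2 = NA_real_, kind = kind,
                          half_window = half_window),
                     class = "peak_site_profile"))
  win <- substring(pk$sequence, pk$center_offset - half_window + 1L,
                   pk$center_offset + half_window + 1L)
  tx <- transcript_set(transcript_id = pk$peak_id, gene_id = pk$peak_id,
                       sequence = win, utr5_end = 0L, cds_end = 0L)
  hits <- scan_sites(mirna, tx, params = params, kinds = kind)
  offs <- if (nrow(hits) > 0L) {
    data.frame(peak_id = hits$transcript_id, site_class = hits$site_class,
               offset = .site_midpoint(hits$start, hits$end) - half_window,
               stringsAsFactors = FALSE)
  } else {
    data.frame(peak_id = character(0), site_class = character(0),
               offset = integer(0), stringsAsFactors = FALSE)
  }
  presence <- stats::setNames(pk$peak_id %in% offs$peak_id, pk$peak_id)
  g2 <- if (nrow(offs) >= 4L && stats::var(offs$offset) > 0)
    excess_kurtosis(offs$offset) else NA_real_
  structure(list(offsets = offs, presence = presence,
                 n_sites = nrow(offs), g2 = g2, kind = kind,
                 half_window = half_window),
            class = "peak_site_profile")
}

#' Excess kurtosis (population-moment estimator)
#'
#' \code{g2 = m4 / m2^2 - 3} with \code{m_k} the k-th central sample
#' moment.  Positive values indicate a distribution more peaked than the
#' normal; for site offsets, concentration at the peak center.
#'
#' @param values Numeric vector, length >= 4, non-constant.
#' @return The excess kurtosis.
#' @export
excess_kurtosis <- function(values) {
  n <- length(values)
  if (n < 4L) stop("need at least 4 values", call. = FALSE)
  m <- mean(values)
  m2 <- mean((values - m)^2)
  if (m2 == 0) stop("constant vector has undefined kurtosis", call. = FALSE)
  m4 <- mean((values - m)^4)
  m4 / m2^2 - 3
}

#' Site enrichment in differentially detected peaks
#'
#' One-sided Fisher exact test of the 2x2 table (differential status x
#' site presence) over the scanned peaks.
#'
#' @param peaks The \code{\link{peak_set}} (only peaks named in
#'   \code{presence} are used).
#' @param presence Named logical vector from \code{\link{site_offsets}}.
#' @return A \code{\link{fisher_exact_upper}} result.
#' @export
differential_peak_site_test <- function(peaks, presence) {
  stopifnot(inherits(peaks, "peak_set"))
  idx <- match(names(presence), peaks$peak_id)
  if (anyNA(idx)) stop("presence names must be peak ids", call. = FALSE)
  diff <- peaks$differential[idx]
  if (!any(diff) || all(diff))
    stop("need both differential and unchanged peaks", call. = FALSE)
  res <- fisher_exact_upper(c(sum(diff & presence), sum(diff & !presence),
                              sum(!diff & presence), sum(!diff & !presence)))
  res$n <- length(presence)
  res
}
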