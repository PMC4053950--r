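## Container constructors.  Both containers are plain data frames with a
## class attribute; columns are the contract, methods stay thin.

#' Construct a set of miRNAs
#'
#' @param mirna_id Character vector of unique identifiers.
#' @param sequence Mature miRNA sequences 5'->3' (T is converted to U).
#'   Sequences shorter than 15 nt cannot carry the full set of three
#'   centered windows and trigger a warning (they still scan with the
#'   windows that fit); shorter than 8 nt is an error.
#' @return A data.frame of class \code{mirna_set} with columns
#'   \code{mirna_id}, \code{sequence}, \code{length}.
#' @export
mirna_set <- function(mirna_id, sequence) {
  if (anyDuplicated(mirna_id))
    stop("duplicate miRNA id: ", mirna_id[duplicated(mirna_id)][1L],
         call. = FALSE)
  sequence <- normalize_rna(sequence, what = "miRNA sequence")
  len <- nchar(sequence)
  if (any(len < 8L))
    stop("miRNA ", mirna_id[len < 8L][1L], " is shorter than 8 nt",
         call. = FALSE)
  if (any(len < 15L))
    warning("miRNA(s) shorter than 15 nt: not all centered windows fit",
            call. = FALSE)
  out <- data.frame(mirna_id = as.character(mirna_id),
                    sequence = sequence,
                    length = len,
                    stringsAsFactors = FALSE)
  class(out) <- c("mirna_set", "data.frame")
  out
}

#' Construct a set of transcript models
#'
#' A transcript is a 5'->3' RNA sequence partitioned into 5'UTR =
#' [0, utr5_end), CDS = [utr5_end, cds_end) and 3'UTR = [cds_end, length)
#' with 0-based half-open coordinates.  Exactly one transcript per gene is
#' canonical: the longest (ties broken by id).  Supplied canonical flags
#' are checked against that rule; a gene with no valid flag gets the
#' longest transcript auto-flagged with a warning.
#'
#' @param transcript_id,gene_id Character vectors.
#' @param sequence Transcript sequences (T converted to U).
#' @param utr5_end,cds_end 0-based region boundaries, with
#'   \code{0 <= utr5_end <= cds_end <= nchar(sequence)}.
#' @param is_canonical Optional logical vector; \code{NULL} auto-assigns.
#' @param validate Normalise and validate the sequence alphabet (default
#'   TRUE; the simulator, whose sequences are RNA by construction, skips
#'   this).
#' @return A data.frame of class \code{transcript_set} with columns
#'   transcript_id, gene_id, sequence, utr5_end, cds_end, length,
#'   is_canonical.
#' @export
transcript_set <- function(transcript_id, gene_id, sequence,
                           utr5_end, cds_end, is_canonical = NULL,
                           validate = TRUE) {
  transcript_id <- as.character(transcript_id)
  gene_id <- as.character(gene_id)
  if (anyDuplicated(transcript_id))
    stop("duplicate transcript id: ",
         transcript_id[duplicated(transcript_id)][1L], call. = FALSE)
  if (validate)
    sequence <- normalize_rna(sequence, what = "transcript sequence")
  len <- nchar(sequence)
  utr5_end <- as.integer(utr5_end)
  cds_end <- as.integer(cds_end)
  bad <- which(utr5_end < 0L | utr5_end > cds_end | cds_end > len)
  if (length(bad) > 0L)
    stop(sprintf(
      "invalid region boundaries for %s: need 0 <= utr5_end <= cds_end <= length",
      transcript_id[bad[1L]]), call. = FALSE)

  longest <- .longest_per_gene(transcript_id, gene_id, len)
  if (is.null(is_canonical)) {
    is_canonical <- transcript_id %in% longest
  } else {
    is_canonical <- as.logical(is_canonical)
    for (g in unique(gene_id)) {
      idx <- which(gene_id == g)
      flagged <- idx[is_canonical[idx]]
      want <- longest[match(g, unique(gene_id))]
      want_idx <- which(transcript_id == want)
      if (length(flagged) != 1L || flagged != want_idx) {
        warning(sprintf(
          "gene %s: canonical flag missing or not on the longest transcript; auto-flagging %s",
          g, want), call. = FALSE)
        is_canonical[idx] <- FALSE
        is_canonical[want_idx] <- TRUE
      }
    }
  }
  out <- data.frame(transcript_id = transcript_id, gene_id = gene_id,
                    sequence = sequence, utr5_end = utr5_end,
                    cds_end = cds_end, length = len,
                    is_canonical = is_canonical, stringsAsFactors = FALSE)
  class(out) <- c("transcript_set", "data.frame")
  out
}

## id of the longest transcript per gene (ties -> first id alphabetically),
## returned in order of unique(gene_id).
.longest_per_gene <- function(transcript_id, gene_id, len) {
  o <- order(gene_id, -len, transcript_id)
  first <- o[!duplicated(gene_id[o])]
  transcript_id[first][match(unique(gene_id), gene_id[first])]
}

#' Region lengths of a transcript set
#' @param transcripts A \code{transcript_set}.
#' @return data.frame with transcript_id and the UTR5/CDS/UTR3 lengths.
#' @export
region_lengths <- function(transcripts) {
  data.frame(transcript_id = transcripts$transcript_id,
             UTR5 = transcripts$utr5_end,
             CDS = transcripts$cds_end - transcripts$utr5_end,
             UTR3 = transcripts$length - transcripts$cds_end,
             stringsAsFactors = FALSE)
}

## region of a 0-based position within one transcript row
.region_of <- function(pos, utr5_end, cds_end) {
  ifelse(pos < utr5_end, "UTR5", ifelse(pos < cds_end, "CDS", "UTR3"))
}

## midpoint index of a site (lower-middle for even widths)
.site_midpoint <- function(start, end) start + (end - start - 1L) %/% 2L
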