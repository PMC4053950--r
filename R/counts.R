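## Per-transcript site count/density tables: the covariates of the
## logistic enrichment model (one column per site class x region).

.count_cols <- function() {
  as.vector(outer(SITE_CLASSES, REGIONS, function(a, b) paste0("count_", a, "_", b)))
}
.dens_cols <- function() sub("^count_", "dens_", .count_cols())

#' Tabulate site counts and densities per transcript region
#'
#' Builds one row per (transcript, miRNA) with, for each (site class,
#' region) pair, the number of sites whose midpoint falls in the region and
#' the density in sites per kilobase of region.  Zero-length regions get
#' density 0 and a zero-length flag.  Transcripts or miRNAs without any
#' site are included as all-zero rows.
#'
#' @param matches Site matches from \code{\link{scan_sites}}.
#' @param transcripts The \code{\link{transcript_set}} scanned.
#' @param mirna_ids miRNA ids to tabulate (default: those in
#'   \code{matches}).
#' @return data.frame of class \code{site_count_table}: transcript_id,
#'   mirna_id, gene_id, is_canonical, region lengths \code{len_*},
#'   zero-length flags \code{zero_len_*}, and \code{count_*}/\code{dens_*}
#'   columns for all 7 classes x 3 regions.
#' @export
site_count_table <- function(matches, transcripts,
                             mirna_ids = unique(matches$mirna_id)) {
  stopifnot(inherits(transcripts, "transcript_set"))
  if (length(mirna_ids) == 0L) mirna_ids <- "miRNA"
  if (nrow(matches) > 0L) {
    ti <- match(matches$transcript_id, transcripts$transcript_id)
    if (anyNA(ti))
      stop("matches reference transcripts absent from the transcript set",
           call. = FALSE)
    if (any(matches$start < 0L | matches$end > transcripts$length[ti]))
      stop("match coordinates outside transcript bounds", call. = FALSE)
  }

  keys <- as.vector(outer(transcripts$transcript_id, mirna_ids, paste,
                          sep = "\r"))
  cols <- paste0(rep(SITE_CLASSES, times = 3L),
                 "_", rep(REGIONS, each = length(SITE_CLASSES)))
  if (nrow(matches) > 0L) {
    mk <- paste(matches$transcript_id, matches$mirna_id, sep = "\r")
    mc <- paste0(matches$site_class, "_", matches$region)
    tab <- table(factor(mk, levels = keys), factor(mc, levels = cols))
  } else {
    tab <- matrix(0L, nrow = length(keys), ncol = length(cols),
                  dimnames = list(keys, cols))
  }
  counts <- matrix(as.integer(tab), nrow = length(keys),
                   dimnames = list(NULL, paste0("count_", cols)))

  n_tx <- nrow(transcripts)
  tx_rep <- rep(seq_len(n_tx), times = length(mirna_ids))
  rl <- region_lengths(transcripts)
  len <- as.matrix(rl[tx_rep, REGIONS, drop = FALSE])
  len_by_col <- len[, rep(seq_along(REGIONS), each = length(SITE_CLASSES)),
                    drop = FALSE]
  dens <- ifelse(len_by_col > 0L, counts * 1000 / len_by_col, 0)
  colnames(dens) <- paste0("dens_", cols)

  out <- data.frame(
    transcript_id = transcripts$transcript_id[tx_rep],
    mirna_id = rep(mirna_ids, each = n_tx),
    gene_id = transcripts$gene_id[tx_rep],
    is_canonical = transcripts$is_canonical[tx_rep],
    len_UTR5 = len[, "UTR5"], len_CDS = len[, "CDS"], len_UTR3 = len[, "UTR3"],
    zero_len_UTR5 = len[, "UTR5"] == 0L,
    zero_len_CDS = len[, "CDS"] == 0L,
    zero_len_UTR3 = len[, "UTR3"] == 0L,
    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(counts), as.data.frame(dens))
  class(out) <- c("site_count_table", "data.frame")
  rownames(out) <- NULL
  out
}

#' @rdname site_count_table
#' @param transcript A one-row \code{transcript_set}.
#' @export
count_sites_by_region <- function(matches, transcript) {
  stopifnot(nrow(transcript) == 1L)
  if (nrow(matches) > 0L && !all(matches$transcript_id == transcript$transcript_id))
    stop("matches do not all belong to the given transcript", call. = FALSE)
  site_count_table(matches, transcript)
}

#' Site classes present in a count-table row
#'
#' A transcript is "exclusive-OK" when at most one distinct site class is
#' present anywhere in it; analyses of shared targets drop transcripts
#' carrying multiple different site types.
#'
#' @param row One row of a \code{\link{site_count_table}}.
#' @return List with \code{classes} (character vector of classes present)
#'   and \code{exclusive_ok} (logical).
#' @export
transcript_site_classes <- function(row) {
  stopifnot(nrow(row) == 1L)
  present <- vapply(SITE_CLASSES, function(cl) {
    sum(as.numeric(row[paste0("count_", cl, "_", REGIONS)])) > 0
  }, logical(1))
  list(classes = SITE_CLASSES[present],
       exclusive_ok = sum(present) <= 1L)
}

## number of distinct classes present, vectorised over table rows
.n_classes_present <- function(tab) {
  present <- vapply(SITE_CLASSES, function(cl) {
    rowSums(as.matrix(tab[paste0("count_", cl, "_", REGIONS)])) > 0
  }, logical(nrow(tab)))
  rowSums(matrix(present, nrow = nrow(tab)))
}

## transcripts with >= 1 site of a class (any region), vectorised
.has_class <- function(tab, site_class) {
  rowSums(as.matrix(tab[paste0("count_", site_class, "_", REGIONS)])) > 0
}

#' Proportion of target transcripts carrying each site type
#'
#' For a set of target transcripts, reports the proportion with at least
#' one site of each class, plus cumulative proportions: any seed site, any
#' centered site, and any site at all (the figure-of-merit "how many
#' targets do the site types explain").
#'
#' @param target_transcripts Character vector of transcript ids (must be
#'   rows of \code{tables}).
#' @param tables A \code{\link{site_count_table}} (one miRNA).
#' @return data.frame with columns \code{what} and \code{proportion};
#'   classes first, then ANY_SEED, ANY_CENTERED, ANY.
#' @export
summarize_site_coverage <- function(target_transcripts, tables) {
  if (length(target_transcripts) == 0L)
    stop("empty target set", call. = FALSE)
  idx <- match(target_transcripts, tables$transcript_id)
  if (anyNA(idx))
    stop("target transcripts missing from the count table", call. = FALSE)
  sub <- tables[idx, , drop = FALSE]
  per_class <- vapply(SITE_CLASSES, function(cl) mean(.has_class(sub, cl)),
                      numeric(1))
  seed_any <- rowSums(matrix(vapply(SITE_CLASSES[1:3], function(cl)
    .has_class(sub, cl), logical(nrow(sub))), nrow = nrow(sub))) > 0
  cen_any <- rowSums(matrix(vapply(SITE_CLASSES[4:7], function(cl)
    .has_class(sub, cl), logical(nrow(sub))), nrow = nrow(sub))) > 0
  data.frame(
    what = c(SITE_CLASSES, "ANY_SEED", "ANY_CENTERED", "ANY"),
    proportion = c(per_class, mean(seed_any), mean(cen_any),
                   mean(seed_any | cen_any)),
    stringsAsFactors = FALSE)
}
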