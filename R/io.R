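## Readers and writers.  All tables are TSV with LF endings; floats are
## serialised with 6 significant digits (p/q-values in scientific
## notation); transcript coordinates 0-based half-open, miRNA positions
## 1-based.  Writers are deterministic so identical inputs give
## byte-identical files.

#' Read a FASTA file of RNA (or DNA) sequences
#'
#' Ids are taken up to the first whitespace; sequences are uppercased with
#' T converted to U and validated against the RNA alphabet.
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids))
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1L], call. = FALSE)
  seqs <- as.character(ss)
  if (any(nchar(seqs) == 0L))
    stop("empty sequence for id ", ids[nchar(seqs) == 0L][1L], call. = FALSE)
  seqs <- vapply(seq_along(seqs), function(i) {
    tryCatch(normalize_rna(seqs[i], what = paste0("record '", ids[i], "'")),
             error = function(e) stop(conditionMessage(e), call. = FALSE))
  }, character(1))
  stats::setNames(seqs, ids)
}

#' Write sequences as FASTA (60-column wrap)
#' @param seqs Named character vector.
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Read a transcript region table and assemble transcript models
#'
#' The table must have columns transcript_id, gene_id, utr5_end, cds_end,
#' is_canonical (0-based half-open boundaries).  Boundaries are validated
#' against the FASTA sequence lengths; canonical flags are validated (one
#' per gene, the longest) with auto-repair and a warning.
#'
#' @param path Region TSV.
#' @param sequences Named character vector from \code{\link{read_fasta}}.
#' @return A \code{\link{transcript_set}}.
#' @export
read_region_table <- function(path, sequences) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#")
  need <- c("transcript_id", "gene_id", "utr5_end", "cds_end", "is_canonical")
  if (!all(need %in% names(tab)))
    stop("region table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  missing <- setdiff(tab$transcript_id, names(sequences))
  if (length(missing) > 0L)
    stop("transcript in region table absent from FASTA: ", missing[1L],
         call. = FALSE)
  transcript_set(tab$transcript_id, tab$gene_id,
                 sequences[tab$transcript_id],
                 tab$utr5_end, tab$cds_end,
                 is_canonical = as.logical(tab$is_canonical))
}

#' Read replicate expression data
#'
#' @param expr_path TSV with a \code{probe_id} column followed by one
#'   numeric column per sample.
#' @param samples_path TSV with columns \code{sample_id}, \code{group}
#'   (PULLDOWN/CONTROL) covering every sample column.
#' @param detection_path Optional TSV, same layout as \code{expr_path},
#'   of detection p-values.
#' @param log2_scale Whether intensities are already log2.
#' @return An \code{\link{expression_matrix}}.
#' @export
read_expression_table <- function(expr_path, samples_path,
                                  detection_path = NULL,
                                  log2_scale = FALSE) {
  expr <- utils::read.delim(expr_path, stringsAsFactors = FALSE,
                            comment.char = "#", check.names = FALSE)
  if (names(expr)[1L] != "probe_id")
    stop("expression table must start with a probe_id column", call. = FALSE)
  samples <- utils::read.delim(samples_path, stringsAsFactors = FALSE,
                               comment.char = "#")
  sample_ids <- names(expr)[-1L]
  grp <- samples$group[match(sample_ids, samples$sample_id)]
  if (anyNA(grp))
    stop("sample column without group assignment: ",
         sample_ids[is.na(grp)][1L], call. = FALSE)
  x <- as.matrix(expr[, -1L, drop = FALSE])
  if (!is.numeric(x)) {
    bad <- which(!vapply(expr[-1L], is.numeric, logical(1)))[1L]
    stop("non-numeric intensities in column ", sample_ids[bad], call. = FALSE)
  }
  rownames(x) <- expr$probe_id
  dp <- NULL
  if (!is.null(detection_path)) {
    det <- utils::read.delim(detection_path, stringsAsFactors = FALSE,
                             comment.char = "#", check.names = FALSE)
    dp <- as.matrix(det[, -1L, drop = FALSE])
    rownames(dp) <- det$probe_id
    dp <- dp[rownames(x), colnames(x), drop = FALSE]
  }
  expression_matrix(x, grp, detection_p = dp, log2_scale = log2_scale)
}

#' Read AGO peaks
#'
#' Either a combined TSV (columns peak_id, sequence, center_offset,
#' differential) or a BED6 file plus a FASTA of peak sequences keyed by
#' peak name, with the differential flag in the BED score column (0/1)
#' and the center defaulting to the interval midpoint.
#'
#' @param path TSV or BED file.
#' @param fasta Optional FASTA path (required for BED input).
#' @return A \code{\link{peak_set}}.
#' @export
read_peaks <- function(path, fasta = NULL) {
  head_lines <- readLines(path, n = 10L)
  first <- head_lines[!grepl("^#", head_lines)][1L]
  if (grepl("^peak_id\t", first)) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             comment.char = "#")
    return(peak_set(tab$peak_id, tab$sequence,
                    center_offset = tab$center_offset,
                    differential = as.logical(tab$differential)))
  }
  bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 6L) stop("BED input needs 6 columns", call. = FALSE)
  names(bed)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
  if (any(bed$end <= bed$start))
    stop("BED interval with end <= start: ", bed$name[bed$end <= bed$start][1L],
         call. = FALSE)
  if (is.null(fasta)) stop("BED peaks need a companion FASTA", call. = FALSE)
  seqs <- read_fasta(fasta)
  missing <- setdiff(bed$name, names(seqs))
  if (length(missing) > 0L)
    stop("missing sequence for peak ", missing[1L], call. = FALSE)
  len <- bed$end - bed$start
  got <- nchar(seqs[bed$name])
  if (any(got != len))
    stop("sequence length does not match interval for peak ",
         bed$name[got != len][1L], call. = FALSE)
  peak_set(bed$name, seqs[bed$name],
           center_offset = (len - 1L) %/% 2L,
           differential = bed$score != 0)
}

## ---- deterministic table writing ----------------------------------------

.fmt_num <- function(x, scientific = FALSE) {
  if (scientific) sprintf("%.6e", x) else
    ifelse(x == round(x) & abs(x) < 1e15, sprintf("%d", as.integer(round(x))),
           sprintf("%.6g", x))
}

#' Write a data.frame as a deterministic TSV
#'
#' Fixed column order as given, LF endings, floats with 6 significant
#' digits; columns named in \code{scientific} (by default p/q-value
#' columns) use scientific notation.  A header comment states the
#' coordinate conventions.
#'
#' @param df data.frame.
#' @param path Output path.
#' @param scientific Column names to serialise in scientific notation.
#' @export
write_tsv <- function(df, path, scientific = intersect(c("p", "q", "lrt_p"),
                                                       names(df))) {
  out <- df
  for (nm in names(out)) {
    if (is.numeric(out[[nm]]) && !is.integer(out[[nm]])) {
      out[[nm]] <- .fmt_num(out[[nm]], scientific = nm %in% scientific)
    }
    if (is.logical(out[[nm]])) out[[nm]] <- ifelse(out[[nm]], 1L, 0L)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("# coordinates: transcript 0-based half-open; miRNA positions 1-based",
             con, sep = "\n")
  writeLines(paste(names(out), collapse = "\t"), con, sep = "\n")
  if (nrow(out) > 0L) {
    lines <- do.call(paste, c(unname(as.list(out)), sep = "\t"))
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

#' Read a TSV written by \code{\link{write_tsv}}
#' @param path File path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                    check.names = FALSE)
}

#' Write site matches as BED6
#'
#' Name = site class, score = number of perfect Watson-Crick pairs
#' (11 - n_mm - n_gu for centered sites), strand "+"; the "chromosome" is
#' the transcript id (transcript-space coordinates).
#'
#' @param matches Site match data.frame from \code{\link{scan_sites}}.
#' @param path Output path.
#' @export
write_sites_bed <- function(matches, path) {
  width <- matches$end - matches$start
  score <- width - matches$n_mm - matches$n_gu
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t+",
                   matches$transcript_id, matches$start, matches$end,
                   matches$site_class, score)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
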