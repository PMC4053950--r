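#' @keywords internal
#' @useDynLib censite, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

## RNA alphabet, base-pair classification and sequence encoding used by the
## scanners.  All sequences are handled 5'->3'; DNA input (T) is normalised
## to RNA (U) on load and the alphabet is strictly {A,C,G,U} afterwards.

RNA_BASES <- c("A", "C", "G", "U")

#' Site classes recognised by the scanners
#'
#' Seed classes follow the TargetScanS conventions (8mer, 7mer-m8, 7mer-A1;
#' 6mers are not counted).  Centered classes describe an 11-nt duplex
#' beginning at miRNA position 3, 4 or 5: perfect Watson-Crick (WC 0MM),
#' with G:U wobble (GU 0MM), and either with one internal mismatch
#' (WC 1MM / GU 1MM).  Classes are mutually exclusive labels.
#' @format Character vector of the seven class labels, most stringent first
#'   within each family.
#' @export
SITE_CLASSES <- c("SEED_8MER", "SEED_7MER_M8", "SEED_7MER_A1",
                  "CEN_WC_0MM", "CEN_GU_0MM", "CEN_WC_1MM", "CEN_GU_1MM")

#' Transcript regions
#' @format Character vector: 5'UTR, CDS, 3'UTR.
#' @export
REGIONS <- c("UTR5", "CDS", "UTR3")

## Stringency rank used when overlapping hits are merged (lower = keep).
.CLASS_RANK <- stats::setNames(seq_along(SITE_CLASSES), SITE_CLASSES)

## byte -> integer code (A=1, C=2, G=3, U=4); anything else maps to 5 and
## can never pair, which is what makes the concatenated-scan separator work.
.ENC_MAP <- local({
  m <- rep(5L, 256L)
  m[utf8ToInt("A")] <- 1L
  m[utf8ToInt("C")] <- 2L
  m[utf8ToInt("G")] <- 3L
  m[utf8ToInt("U")] <- 4L
  m
})

## pair-class matrix indexed [miRNA base, mRNA base]: 2 = Watson-Crick,
## 1 = G:U wobble, 0 = mismatch, -100 = non-base (poisons any window sum).
.PC <- local({
  p <- matrix(0L, 5, 5)
  p[1, 4] <- 2L; p[4, 1] <- 2L; p[3, 2] <- 2L; p[2, 3] <- 2L  # A:U U:A G:C C:G
  p[3, 4] <- 1L; p[4, 3] <- 1L                                # G:U U:G
  p[5, ] <- -100L; p[, 5] <- -100L
  p
})

## Watson-Crick complement on the integer code.
.COMP <- c(4L, 3L, 2L, 1L)

.encode_rna <- function(seq) .ENC_MAP[utf8ToInt(seq)]

#' Normalise a nucleotide string to the RNA alphabet
#'
#' Uppercases, converts T to U and validates that only A/C/G/U remain.
#'
#' @param x Character vector of sequences.
#' @param what Label used in error messages.
#' @return Character vector of validated RNA sequences.
#' @export
normalize_rna <- function(x, what = "sequence") {
  x <- chartr("t", "T", toupper(x))
  x <- chartr("T", "U", x)
  bad <- regmatches(x, regexpr("[^ACGU]", x))
  if (length(unlist(bad)) > 0L) {
    sym <- unlist(bad)[1L]
    stop(sprintf("invalid character '%s' in %s: only A/C/G/U (or T) allowed",
                 sym, what), call. = FALSE)
  }
  x
}

#' Reverse complement of an RNA sequence
#' @param x Character vector of RNA sequences (A/C/G/U).
#' @return Reverse complements, 5'->3'.
#' @export
rna_revcomp <- function(x) {
  vapply(x, function(s) {
    intToUtf8(rev(utf8ToInt(chartr("ACGU", "UGCA", s))))
  }, character(1), USE.NAMES = FALSE)
}

#' Classify a single miRNA:mRNA base pair
#'
#' Watson-Crick pairs are A:U, U:A, G:C, C:G; G:U and U:G are wobble pairs
#' (pairing-competent in centered-site matching); everything else is a
#' mismatch.
#'
#' @param mirna_base,mrna_base Single RNA bases (vectorised).
#' @return Character vector with elements "WC", "GU" or "MM".
#' @export
#' @examples
#' pair_class("G", "C")  # WC
#' pair_class("G", "U")  # GU
pair_class <- function(mirna_base, mrna_base) {
  a <- .ENC_MAP[utf8ToInt(paste(mirna_base, collapse = ""))]
  b <- .ENC_MAP[utf8ToInt(paste(mrna_base, collapse = ""))]
  if (length(a) != length(b))
    stop("base vectors must have equal length", call. = FALSE)
  if (any(a == 5L)) {
    stop(sprintf("invalid RNA base '%s'", mirna_base[which(a == 5L)[1L]]),
         call. = FALSE)
  }
  if (any(b == 5L)) {
    stop(sprintf("invalid RNA base '%s'", mrna_base[which(b == 5L)[1L]]),
         call. = FALSE)
  }
  c("MM", "GU", "WC")[.PC[cbind(a, b)] + 1L]
}
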