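## Pull-down enrichment calling: detection filtering, normalisation,
## an empirical-Bayes moderated t statistic (one-sided, enrichment
## direction), Benjamini-Hochberg FDR, and target-set assembly.

#' Construct a replicate expression matrix
#'
#' @param intensities Numeric matrix, probes x samples, with rownames
#'   (probe ids) and colnames (sample ids).
#' @param groups Character vector (one per sample) with values "PULLDOWN"
#'   or "CONTROL".
#' @param detection_p Optional matrix of per-probe per-sample detection
#'   p-values, same dimensions as \code{intensities}.
#' @param log2_scale Are the intensities already log2 (default FALSE =
#'   linear scale)?
#' @return List of class \code{expression_matrix}.
#' @export
expression_matrix <- function(intensities, groups, detection_p = NULL,
                              log2_scale = FALSE) {
  intensities <- as.matrix(intensities)
  if (is.null(rownames(intensities)))
    stop("intensity matrix needs probe ids as rownames", call. = FALSE)
  groups <- as.character(groups)
  if (length(groups) != ncol(intensities))
    stop("one group label per sample column required", call. = FALSE)
  if (!all(groups %in% c("PULLDOWN", "CONTROL")))
    stop("groups must be PULLDOWN or CONTROL", call. = FALSE)
  if (anyNA(intensities))
    stop("missing intensities are not allowed", call. = FALSE)
  if (!is.null(detection_p)) {
    detection_p <- as.matrix(detection_p)
    if (!identical(dim(detection_p), dim(intensities)))
      stop("detection_p must match the intensity matrix dimensions",
           call. = FALSE)
    if (any(detection_p < 0 | detection_p > 1))
      stop("detection p-values must lie in [0, 1]", call. = FALSE)
  }
  structure(list(intensities = intensities, groups = groups,
                 detection_p = detection_p, log2_scale = isTRUE(log2_scale)),
            class = "expression_matrix")
}

#' Filter probes by detection above background
#'
#' Retains exactly the probes whose detection p-value is below
#' \code{alpha} in every control sample (probes must be reliably detected
#' in the baseline condition to be testable for pull-down enrichment).
#'
#' @param em An \code{\link{expression_matrix}} with detection p-values.
#' @param alpha Detection threshold (default 0.01).
#' @return The filtered \code{expression_matrix}.
#' @export
detection_filter <- function(em, alpha = 0.01) {
  stopifnot(inherits(em, "expression_matrix"))
  if (is.null(em$detection_p))
    stop("no detection p-values attached", call. = FALSE)
  ctrl <- em$groups == "CONTROL"
  if (!any(ctrl)) stop("no control samples", call. = FALSE)
  keep <- rowSums(em$detection_p[, ctrl, drop = FALSE] < alpha) == sum(ctrl)
  em$intensities <- em$intensities[keep, , drop = FALSE]
  em$detection_p <- em$detection_p[keep, , drop = FALSE]
  em
}

#' Log2-transform and quantile-normalise intensities
#'
#' Linear intensities are log2-transformed, then quantile normalisation
#' maps every sample onto the mean of the per-sample sorted value vectors,
#' so the sorted values of all samples are identical afterwards and the
#' within-sample rank order is preserved (ties broken by row order).
#'
#' @param em An \code{\link{expression_matrix}} on the linear scale.
#' @return The normalised \code{expression_matrix} (\code{log2_scale} set).
#' @export
normalize_expression <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  x <- em$intensities
  if (!em$log2_scale) {
    if (any(x <= 0)) {
      idx <- which(x <= 0, arr.ind = TRUE)[1L, ]
      stop(sprintf("non-positive intensity for probe %s, sample %s",
                   rownames(x)[idx[1L]], colnames(x)[idx[2L]]),
           call. = FALSE)
    }
    x <- log2(x)
  }
  sorted_mean <- rowMeans(apply(x, 2L, sort))
  out <- apply(x, 2L, function(col)
    sorted_mean[rank(col, ties.method = "first")])
  dimnames(out) <- dimnames(x)
  em$intensities <- out
  em$log2_scale <- TRUE
  em
}

## Invert the trigamma function by bracketed uniroot (trigamma is
## strictly decreasing on (0, Inf)).
.trigamma_inverse <- function(x) {
  if (!is.finite(x) || x <= 0) return(Inf)
  if (x > trigamma(1e-4)) return(1e-4)
  if (x < trigamma(1e8)) return(1e8)
  stats::uniroot(function(y) trigamma(y) - x, lower = 1e-4, upper = 1e8,
                 tol = 1e-10)$root
}

## Moment-match a scaled-F hyperprior to observed sample variances:
## log s^2 has mean log s0^2 + digamma(d/2) - log(d/2) shifted by the
## prior, and excess variance over trigamma(d/2) identifies d0.
.fit_variance_prior <- function(s2, d) {
  ok <- is.finite(s2) & s2 > 0
  z <- log(s2[ok])
  e <- z - digamma(d / 2) + log(d / 2)
  n <- length(e)
  if (n < 2L) return(list(d0 = NA_real_, s02 = NA_real_))
  evar <- stats::var(e) - trigamma(d / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * .trigamma_inverse(evar)
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(mean(e))
  }
  list(d0 = d0, s02 = s02)
}

#' Moderated t test for pull-down enrichment
#'
#' Per-probe two-sample comparison (PULLDOWN minus CONTROL on the log2
#' scale) with empirical-Bayes variance moderation: per-probe sample
#' variances are shrunk towards a prior \code{s02} with \code{d0} prior
#' degrees of freedom fitted by moment matching on the log sample
#' variances; the posterior variance is
#' \code{(d0*s02 + d*s2) / (d0 + d)} and the t statistic has
#' \code{d0 + d} degrees of freedom.  P-values are one-sided upper tail
#' (enrichment direction only).
#'
#' @param em A normalised \code{\link{expression_matrix}} (log2 scale).
#' @param fdr FDR threshold used to set the \code{enriched} flag
#'   (default 0.05).
#' @param d0,s02 Optional overrides of the fitted hyper-parameters
#'   (\code{d0 = 0} gives the ordinary t test; \code{d0 = Inf} a z-like
#'   statistic with variance \code{s02}).
#' @return data.frame of class \code{enrichment_result} with columns
#'   probe_id, logFC, t, df, p, q, enriched; hyper-parameters in
#'   attributes \code{d0}, \code{s02}, \code{fallback}.
#' @export
moderated_t_enrichment <- function(em, fdr = 0.05, d0 = NULL, s02 = NULL) {
  stopifnot(inherits(em, "expression_matrix"))
  if (!em$log2_scale)
    stop("intensities must be log2 scale (run normalize_expression)",
         call. = FALSE)
  x <- em$intensities
  pull <- em$groups == "PULLDOWN"
  ctrl <- em$groups == "CONTROL"
  n1 <- sum(pull); n2 <- sum(ctrl)
  if (n1 < 2L || n2 < 2L)
    stop("need >= 2 replicates per group", call. = FALSE)
  d <- n1 + n2 - 2L

  xp <- x[, pull, drop = FALSE]
  xc <- x[, ctrl, drop = FALSE]
  mp <- rowMeans(xp); mc <- rowMeans(xc)
  logFC <- mp - mc
  ss <- rowSums((xp - mp)^2) + rowSums((xc - mc)^2)
  s2 <- ss / d
  if (all(s2 == 0))
    stop("all probes have zero within-group variance", call. = FALSE)

  fallback <- FALSE
  if (is.null(d0) || is.null(s02)) {
    prior <- .fit_variance_prior(s2, d)
    if (is.null(d0)) d0 <- prior$d0
    if (is.null(s02)) s02 <- prior$s02
    if (!is.finite(d0) && !identical(d0, Inf) || is.na(d0)) {
      warning("variance-prior fit failed; falling back to ordinary t",
              call. = FALSE)
      d0 <- 0; s02 <- 0; fallback <- TRUE
    }
  }

  if (is.infinite(d0)) {
    st2 <- rep(s02, length(s2)); df <- Inf
  } else if (d0 == 0) {
    st2 <- s2; df <- d
  } else {
    st2 <- (d0 * s02 + d * s2) / (d0 + d); df <- d0 + d
  }
  se <- sqrt(st2 * (1 / n1 + 1 / n2))
  t <- ifelse(se > 0, logFC / se, ifelse(logFC == 0, 0, sign(logFC) * Inf))
  p <- stats::pt(t, df = df, lower.tail = FALSE)
  q <- bh_fdr(p, ids = rownames(x))

  out <- data.frame(probe_id = rownames(x), logFC = logFC, t = t,
                    df = df, p = p, q = q, enriched = q <= fdr,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02
  attr(out, "fallback") <- fallback
  attr(out, "fdr") <- fdr
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; ties are reported stably (equal p gives equal
#' q), and \code{ids} fixes a reproducible output order contract for
#' downstream thresholding.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @param ids Optional ids (unused in the adjustment itself, which depends
#'   only on the p-values, but validated for length).
#' @return Vector of q-values, same order as \code{p}.
#' @export
bh_fdr <- function(p, ids = NULL) {
  if (length(p) == 0L) stop("empty p-value vector", call. = FALSE)
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  if (!is.null(ids) && length(ids) != length(p))
    stop("ids must match p in length", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Assemble the target set of a pull-down
#'
#' Targets are the transcripts exactly matched by probes meeting the FDR
#' threshold.  With \code{exclude_ambiguous}, transcripts that are also
#' matched by a retained but non-enriched probe are moved to the ambiguous
#' set and excluded from the targets.  Enriched probes absent from the
#' probe map are dropped with a message.
#'
#' @param results An \code{\link{moderated_t_enrichment}} result.
#' @param probe_map data.frame with columns \code{probe_id},
#'   \code{transcript_id}.
#' @param fdr FDR threshold (default 0.05).
#' @param exclude_ambiguous Exclude ambiguous transcripts (default TRUE).
#' @param transcripts Optional \code{\link{transcript_set}} used to map
#'   target transcripts to genes.
#' @param mirna_id Optional label for the pull-down's miRNA.
#' @return List of class \code{target_set}: \code{mirna_id},
#'   \code{enriched_probes}, \code{targets}, \code{ambiguous},
#'   \code{genes}.
#' @export
call_targets <- function(results, probe_map, fdr = 0.05,
                         exclude_ambiguous = TRUE, transcripts = NULL,
                         mirna_id = NA_character_) {
  if (is.null(results) || nrow(results) == 0L)
    stop("empty enrichment results", call. = FALSE)
  stopifnot(all(c("probe_id", "transcript_id") %in% names(probe_map)))
  enriched <- results$probe_id[results$q <= fdr]
  unmapped <- setdiff(enriched, probe_map$probe_id)
  if (length(unmapped) > 0L) {
    message(length(unmapped), " enriched probe(s) missing from the probe map; dropped")
    enriched <- setdiff(enriched, unmapped)
  }
  pm <- probe_map[probe_map$probe_id %in% results$probe_id, , drop = FALSE]
  targets <- sort(unique(pm$transcript_id[pm$probe_id %in% enriched]))
  not_enriched <- setdiff(results$probe_id, enriched)
  ambiguous <- character(0)
  if (exclude_ambiguous) {
    also_flat <- unique(pm$transcript_id[pm$probe_id %in% not_enriched])
    ambiguous <- intersect(targets, also_flat)
    targets <- setdiff(targets, ambiguous)
  }
  genes <- character(0)
  if (!is.null(transcripts)) {
    genes <- sort(unique(
      transcripts$gene_id[match(targets, transcripts$transcript_id)]))
    genes <- genes[!is.na(genes)]
  }
  structure(list(mirna_id = mirna_id, enriched_probes = enriched,
                 targets = targets, ambiguous = ambiguous, genes = genes),
            class = "target_set")
}
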