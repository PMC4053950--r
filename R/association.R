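## Association statistics between predicted sites and enrichment status:
## one-sided Fisher exact tests on 2x2 tables, the logistic model of
## enrichment on per-region site counts/densities, Kolmogorov-Smirnov
## fold-change shift tests, and shared-target comparisons.

.target_ids <- function(x) {
  if (inherits(x, "target_set")) x$targets else as.character(x)
}

#' One-sided (upper-tail) Fisher exact test on a 2x2 table
#'
#' The table is \code{[[w, x], [y, z]]} with w = targets with site,
#' x = targets without, y = non-targets with, z = non-targets without.
#' The p-value is the exact hypergeometric upper tail P[X >= w]
#' conditioned on the margins.  The odds ratio is the sample cross-product
#' ratio (w*z)/(x*y), with the Haldane-Anscombe +0.5 applied to all cells
#' when any cell is zero (flagged), and a Woolf logit 95% CI.
#'
#' @param tab 2x2 matrix of non-negative integer counts, or a length-4
#'   vector (w, x, y, z).
#' @return List of class \code{contingency_result}: \code{table},
#'   \code{odds_ratio}, \code{ci_low}, \code{ci_high}, \code{p},
#'   \code{corrected}.
#' @export
fisher_exact_upper <- function(tab) {
  if (is.matrix(tab)) tab <- as.vector(t(tab))
  if (length(tab) != 4L) stop("need a 2x2 table", call. = FALSE)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("cells must be non-negative integers", call. = FALSE)
  w <- tab[1L]; x <- tab[2L]; y <- tab[3L]; z <- tab[4L]
  if (w + x + y + z <= 0) stop("empty table", call. = FALSE)
  if ((w + x) == 0 || (y + z) == 0 || (w + y) == 0 || (x + z) == 0)
    stop("zero margin in 2x2 table", call. = FALSE)
  ## upper tail: at least w of the (w+x) "target" draws carry a site,
  ## drawing from w+y site-carriers among the total
  p <- stats::phyper(w - 1, w + y, x + z, w + x, lower.tail = FALSE)
  corrected <- any(tab == 0)
  cc <- if (corrected) tab + 0.5 else tab
  or <- (cc[1L] * cc[4L]) / (cc[2L] * cc[3L])
  se_log <- sqrt(sum(1 / cc))
  ci <- exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se_log)
  structure(list(table = matrix(as.numeric(c(w, x, y, z)), 2L, byrow = TRUE),
                 odds_ratio = or, ci_low = ci[1L], ci_high = ci[2L],
                 p = p, corrected = corrected),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("2x2 upper-tail exact test: OR = %.3g (95%% CI %.3g-%.3g), p = %.3g%s\n",
              x$odds_ratio, x$ci_low, x$ci_high, x$p,
              if (x$corrected) " [Haldane-Anscombe corrected]" else ""))
  invisible(x)
}

#' Site-type enrichment among pull-down targets
#'
#' Tests whether transcripts with at least one site of \code{site_class}
#' are over-represented among targets relative to the rest of the
#' background (one-sided Fisher exact test).  With \code{exclusive},
#' transcripts carrying more than one distinct site class are removed
#' before tabulation, so any association is attributable to the single
#' class a transcript carries.
#'
#' @param targets A \code{target_set} or character vector of target
#'   transcript ids (subset of \code{background}).
#' @param background Character vector of all testable transcript ids.
#' @param tables A \code{\link{site_count_table}} covering the background.
#' @param site_class One of \code{\link{SITE_CLASSES}}, or a vector of
#'   classes pooled together ("has site" = any of them).
#' @param exclusive Drop multi-class transcripts first (default FALSE).
#' @return A \code{\link{fisher_exact_upper}} result with the cell counts
#'   attached.
#' @export
site_type_enrichment <- function(targets, background, tables, site_class,
                                 exclusive = FALSE) {
  targets <- .target_ids(targets)
  if (!all(targets %in% background))
    stop("targets must be a subset of the background", call. = FALSE)
  idx <- match(background, tables$transcript_id)
  if (anyNA(idx))
    stop("background transcripts missing from the count table", call. = FALSE)
  tab <- tables[idx, , drop = FALSE]
  keep <- rep(TRUE, nrow(tab))
  if (exclusive) keep <- .n_classes_present(tab) <= 1L
  if (!any(keep)) stop("no transcripts left after exclusive-type filtering",
                       call. = FALSE)
  tab <- tab[keep, , drop = FALSE]
  bg <- background[keep]
  has <- rowSums(matrix(vapply(site_class, function(cl) .has_class(tab, cl),
                               logical(nrow(tab))), nrow = nrow(tab))) > 0
  is_t <- bg %in% targets
  res <- fisher_exact_upper(c(sum(is_t & has), sum(is_t & !has),
                              sum(!is_t & has), sum(!is_t & !has)))
  res$site_class <- paste(site_class, collapse = "+")
  res$n <- length(bg)
  res
}

#' Logistic regression of enrichment status on site covariates
#'
#' Fits, by maximum likelihood (iteratively reweighted least squares, the
#' \code{glm} binomial fit), \code{logit(p_i) = b0 + sum_ab b_ab x_ab,i}
#' where \code{x_ab,i} is the count (or density, sites/kb) of class-a
#' sites in region b of transcript i.  Covariates without variation are
#' dropped.  Wald tests per coefficient; Nagelkerke r2 against the
#' intercept-only model.
#'
#' @param status Logical vector of enrichment status, one per row of
#'   \code{tables}.
#' @param tables A \code{\link{site_count_table}}.
#' @param mode Use site \code{"count"} or \code{"density"} covariates.
#' @param classes,regions Site classes and regions to include.
#' @param canonical_only Restrict to the canonical (longest) transcript
#'   per gene.
#' @return List of class \code{regression_fit}: \code{coefficients}
#'   (term/estimate/se/z/p data.frame), \code{L0}, \code{L1}, \code{n},
#'   \code{r2} (Cox-Snell and Nagelkerke), \code{converged},
#'   \code{grad_max}, \code{mode}, \code{dropped}.
#' @export
fit_logistic_sites <- function(status, tables, mode = c("count", "density"),
                               classes = SITE_CLASSES, regions = REGIONS,
                               canonical_only = FALSE) {
  mode <- match.arg(mode)
  status <- as.logical(status)
  if (length(status) != nrow(tables))
    stop("status must align with the count-table rows", call. = FALSE)
  keep <- rep(TRUE, nrow(tables))
  if (canonical_only) keep <- as.logical(tables$is_canonical)
  y <- status[keep]
  prefix <- if (mode == "count") "count_" else "dens_"
  cols <- as.vector(outer(classes, regions,
                          function(a, b) paste0(prefix, a, "_", b)))
  X <- as.matrix(tables[keep, cols, drop = FALSE])
  variable <- apply(X, 2L, function(v) stats::var(v) > 0)
  dropped <- cols[!variable]
  X <- X[, variable, drop = FALSE]
  n <- length(y)
  p_cov <- ncol(X)
  if (n < 10L * (p_cov + 1L))
    warning(sprintf("only %d observations for %d coefficients", n, p_cov + 1L),
            call. = FALSE)

  sep_warn <- FALSE
  fit <- withCallingHandlers(
    if (p_cov > 0L)
      stats::glm.fit(cbind(`(Intercept)` = 1, X), y,
                     family = stats::binomial())
    else
      stats::glm.fit(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")), y,
                     family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  coefs <- fit$coefficients
  if (sep_warn && p_cov > 0L && any(y) && any(!y)) {
    ## error only on genuine separation: a covariate whose ranges for the
    ## two outcomes do not overlap (quasi-separation from sparse counts is
    ## tolerated and surfaced via the convergence flag)
    for (cn in colnames(X)) {
      xv <- X[, cn]
      if (min(xv[y]) > max(xv[!y]) || max(xv[y]) < min(xv[!y]))
        stop("complete separation detected; separating covariate: ", cn,
             call. = FALSE)
    }
  }

  ## Wald standard errors from the observed information X'WX
  eta <- fit$linear.predictors
  mu <- fit$fitted.values
  Xd <- cbind(1, X)
  W <- mu * (1 - mu)
  info <- crossprod(Xd * sqrt(W))
  cov <- tryCatch(solve(info), error = function(e) matrix(NA_real_,
                  ncol(Xd), ncol(Xd)))
  se <- sqrt(diag(cov))
  z <- coefs / se
  pval <- 2 * stats::pnorm(-abs(z))

  loglik <- function(mu) sum(y * log(mu) + (1 - y) * log(1 - mu))
  L1 <- loglik(pmin(pmax(mu, 1e-12), 1 - 1e-12))
  p0 <- mean(y)
  L0 <- loglik(rep(pmin(pmax(p0, 1e-12), 1 - 1e-12), n))
  grad <- crossprod(Xd, y - mu)
  r2 <- nagelkerke_r2(L0, max(L0, L1), n)
  lrt_p <- if (p_cov > 0L)
    stats::pchisq(2 * (L1 - L0), df = p_cov, lower.tail = FALSE) else NA_real_

  structure(list(
    coefficients = data.frame(term = names(coefs), estimate = unname(coefs),
                              se = unname(se), z = unname(z),
                              p = unname(pval), stringsAsFactors = FALSE),
    L0 = L0, L1 = L1, n = n, r2 = r2, lrt_p = lrt_p,
    converged = isTRUE(fit$converged), grad_max = max(abs(grad)),
    mode = mode, dropped = dropped), class = "regression_fit")
}

#' Cox-Snell and Nagelkerke pseudo r-squared
#'
#' \code{r2_cs = 1 - exp(2*(L0 - L1)/n)}, rescaled by its maximum
#' \code{1 - exp(2*L0/n)} to give the Nagelkerke r2 in [0, 1].
#'
#' @param L0,L1 Log-likelihoods of the intercept-only and fitted models
#'   (\code{L1 >= L0}).
#' @param n Number of observations.
#' @return List with \code{cox_snell} and \code{nagelkerke}.
#' @export
nagelkerke_r2 <- function(L0, L1, n) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  if (L1 < L0 - 1e-8) stop("L1 must be >= L0", call. = FALSE)
  r2_cs <- 1 - exp(2 * (L0 - L1) / n)
  denom <- 1 - exp(2 * L0 / n)
  r2_n <- if (denom > 0) r2_cs / denom else 0
  list(cox_snell = max(0, min(1, r2_cs)),
       nagelkerke = max(0, min(1, r2_n)))
}

#' One-sided two-sample Kolmogorov-Smirnov shift test
#'
#' Tests whether the fold changes of the in-set transcripts are
#' stochastically greater than those outside the set (the in-set ECDF
#' lying below the out-set ECDF).
#'
#' @param fc_in_set,fc_out_set Numeric vectors (each of length >= 2) of
#'   log fold changes.
#' @param exact Use the exact small-sample p-value (default FALSE =
#'   asymptotic).
#' @return List with \code{D} and one-sided \code{p}.
#' @export
ks_shift_test <- function(fc_in_set, fc_out_set, exact = FALSE) {
  if (length(fc_in_set) < 2L || length(fc_out_set) < 2L)
    stop("need >= 2 values per sample", call. = FALSE)
  kt <- suppressWarnings(
    stats::ks.test(fc_in_set, fc_out_set, alternative = "less",
                   exact = if (exact) TRUE else FALSE))
  list(D = unname(kt$statistic), p = unname(kt$p.value))
}

#' Over-representation of pull-down targets in an external target list
#'
#' 2x2 of pull-down target status against membership of an externally
#' derived target list, over a stated universe, tested one-sided
#' (upper tail).
#'
#' @param targets \code{target_set} or id vector (subset of universe).
#' @param external_targets Id vector (subset of universe).
#' @param universe Id vector defining the testable universe.
#' @return A \code{\link{fisher_exact_upper}} result.
#' @export
external_set_enrichment <- function(targets, external_targets, universe) {
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  targets <- intersect(.target_ids(targets), universe)
  external_targets <- intersect(external_targets, universe)
  is_t <- universe %in% targets
  is_e <- universe %in% external_targets
  res <- fisher_exact_upper(c(sum(is_t & is_e), sum(is_t & !is_e),
                              sum(!is_t & is_e), sum(!is_t & !is_e)))
  res$n <- length(universe)
  res
}

#' Venn counts of two id sets
#' @param setA,setB Character vectors.
#' @return List with \code{a_only}, \code{b_only}, \code{both}.
#' @export
set_overlap <- function(setA, setB) {
  setA <- unique(setA); setB <- unique(setB)
  list(a_only = length(setdiff(setA, setB)),
       b_only = length(setdiff(setB, setA)),
       both = length(intersect(setA, setB)))
}

#' Shared-target site enrichment for a related miRNA pair
#'
#' For two target sets (e.g. a canonical miRNA and its shifted isomiR,
#' which share centered but not seed sites), tests whether the shared
#' targets (A and B) are more likely to carry a site of \code{site_class}
#' than the targets unique to A, and than those unique to B.  Transcripts
#' with multiple distinct site types are excluded when \code{exclusive}.
#'
#' @param targetsA,targetsB \code{target_set}s or id vectors.
#' @param tables \code{\link{site_count_table}} covering all ids (for the
#'   miRNA whose sites are being tested).
#' @param site_class Class (or pooled classes) to test.
#' @param exclusive Exclusive-type filtering (default TRUE).
#' @return List with elements \code{shared_vs_a_only} and
#'   \code{shared_vs_b_only}, each a \code{contingency_result}.
#' @export
isomir_shared_site_test <- function(targetsA, targetsB, tables, site_class,
                                    exclusive = TRUE) {
  a <- .target_ids(targetsA); b <- .target_ids(targetsB)
  if (length(a) == 0L || length(b) == 0L)
    stop("both target sets must be non-empty", call. = FALSE)
  shared <- intersect(a, b)
  a_only <- setdiff(a, b)
  b_only <- setdiff(b, a)
  if (length(shared) == 0L) stop("no shared targets", call. = FALSE)
  if (length(a_only) == 0L || length(b_only) == 0L)
    stop("one of the unique target sets is empty", call. = FALSE)
  one <- function(unique_set) {
    bg <- c(shared, unique_set)
    site_type_enrichment(shared, bg, tables, site_class,
                         exclusive = exclusive)
  }
  list(shared_vs_a_only = one(a_only), shared_vs_b_only = one(b_only))
}
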