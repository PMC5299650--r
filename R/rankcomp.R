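#' Reversal flags of a single profile against the background
#'
#' For each stable pair, compares the profile's strict beta ordering with
#' the direction stored in the background.  A pair is reversed when the
#' profile's ordering contradicts the stored direction, consistent when it
#' matches, and not evaluable (`NA`) when either site is missing or the
#' two betas are exactly tied.
#'
#' @param background an `"rmo_background"`.
#' @param beta named numeric vector of beta values covering (a subset of)
#'   the background's site universe.
#' @return logical vector aligned with `background$pairs` rows: `TRUE`
#'   reversed, `FALSE` consistent, `NA` not evaluable.
#' @export
sample_reversal_flags <- function(background, beta) {
  p <- background$pairs
  bi <- beta[match(background$sites[p$i], names(beta))]
  bj <- beta[match(background$sites[p$j], names(beta))]
  d <- bi - bj
  flag <- ifelse(p$direction == "i_less", d > 0, d < 0)
  flag[is.na(d) | d == 0] <- NA
  flag
}

#' Per-site reversal contingency table
#'
#' Splits a site's evaluable stable pairs by side and reversal status:
#' among the `a` pairs where the site is the lower member, `a1` are
#' reversed (the site appears to have moved up, supporting
#' hypermethylation); among the `b` pairs where it is the higher member,
#' `b1` are reversed (supporting hypomethylation).  Pairs that are not
#' evaluable in this profile are dropped from both margins.
#'
#' @param background an `"rmo_background"`.
#' @param flags reversal flags from [sample_reversal_flags()] for the same
#'   background.
#' @param site_id one site id.
#' @return list `a1`, `a0`, `b1`, `b0` (`a = a1 + a0`, `b = b1 + b0`).
#' @export
site_contingency <- function(background, flags, site_id) {
  idx <- match(site_id, background$sites)
  if (is.na(idx)) stop("unknown site: ", site_id)
  p <- background$pairs
  lo <- ifelse(p$direction == "i_less", p$i, p$j)
  hi <- ifelse(p$direction == "i_less", p$j, p$i)
  ok <- !is.na(flags)
  a_rows <- ok & lo == idx
  b_rows <- ok & hi == idx
  list(a1 = sum(flags[a_rows]), a0 = sum(!flags[a_rows]),
       b1 = sum(flags[b_rows]), b0 = sum(!flags[b_rows]))
}

#' Two-sided Fisher's exact test for 2x2 tables, vectorised
#'
#' Conditional exact p-value: with the margins fixed, sums the
#' hypergeometric point probabilities of every table whose probability is
#' at most that of the observed table (with relative tolerance `1e-7` on
#' the comparison, as is conventional).  Arguments are the four cells
#' `[[x11, x12], [x21, x22]]` and may be vectors.
#'
#' @param x11,x12,x21,x22 non-negative integer cell counts (vectorised).
#' @return p-values; an all-zero table yields 1 (no information).
#' @examples
#' fisher_exact_two_sided(5, 0, 0, 5)   # 2/252
#' fisher_exact_two_sided(1, 1, 1, 1)   # 1
#' @export
fisher_exact_two_sided <- function(x11, x12, x21, x22) {
  n <- max(length(x11), length(x12), length(x21), length(x22))
  x11 <- rep_len(x11, n); x12 <- rep_len(x12, n)
  x21 <- rep_len(x21, n); x22 <- rep_len(x22, n)
  cells <- cbind(x11, x12, x21, x22)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cells must be non-negative integers")
  vapply(seq_len(n), function(r) {
    a <- x11[r]; m <- x11[r] + x12[r]; nn <- x21[r] + x22[r]
    k <- x11[r] + x21[r]
    if (m + nn == 0L) return(1)
    support <- max(0L, k - nn):min(k, m)
    d <- stats::dhyper(support, m, nn, k)
    obs <- d[match(a, support)]
    min(1, sum(d[d <= obs * (1 + 1e-7)]))
  }, numeric(1))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (delegating to
#' [stats::p.adjust()]), with input validation; the adjusted values map
#' back to the input order.
#'
#' @param p numeric vector of p-values in `[0, 1]` (`NA` passed through).
#' @return adjusted values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Individualized differential-methylation calls for one profile
#'
#' The RankComp scheme: every stable pair whose ordering is reversed in
#' the profile either supports hypermethylation of its lower member or
#' hypomethylation of its higher member.  Under the null that a site is
#' unchanged, reversals implicating it are rank noise from its partners,
#' so the reversal proportions on its two sides should agree; Fisher's
#' exact test on `[[a1, a - a1], [b1, b - b1]]` detects sites whose own
#' shift best explains the disruption.  P-values are BH-adjusted within
#' the profile across the tested sites and calls retained at
#' `fdr < fdr_threshold`, labelled hyper when `a1/a > b1/b`, hypo when
#' `a1/a < b1/b`; an exact proportion tie yields no call.
#'
#' Sites that only ever appear on one side of their stable pairs
#' (`a = 0` or `b = 0`) have no two-sided comparison; by default they are
#' skipped.  With `degenerate = "binomial"` such a site is tested by the
#' exact binomial upper tail of its reversal count under the profile's
#' global reversal rate.
#'
#' @param background an `"rmo_background"`.
#' @param beta named numeric beta vector for one sample.
#' @param fdr_threshold within-sample FDR cutoff (default 0.01).
#' @param restrict_to optional site ids (e.g. population-level DM sites);
#'   only those are tested and BH runs over that set.
#' @param degenerate `"skip"` (default) or `"binomial"`, see Details.
#' @return data frame `site_id`, `direction`, `p`, `fdr` for retained
#'   calls; the number of tested sites in `attr(, "n_tested")`.
#' @export
call_sample_dm <- function(background, beta, fdr_threshold = 0.01,
                           restrict_to = NULL,
                           degenerate = c("skip", "binomial")) {
  degenerate <- match.arg(degenerate)
  if (!inherits(background, "rmo_background"))
    stop("'background' must be an rmo_background")
  if (nrow(background$pairs) == 0L) stop("background has no stable pairs")
  flags <- sample_reversal_flags(background, beta)
  p <- background$pairs
  nsite <- length(background$sites)
  lo <- as.integer(ifelse(p$direction == "i_less", p$i, p$j))
  hi <- as.integer(ifelse(p$direction == "i_less", p$j, p$i))
  ok <- !is.na(flags)
  rev <- ok & flags
  a  <- tabulate(lo[ok],  nbins = nsite)
  b  <- tabulate(hi[ok],  nbins = nsite)
  a1 <- tabulate(lo[rev], nbins = nsite)
  b1 <- tabulate(hi[rev], nbins = nsite)

  testable <- a > 0L & b > 0L
  degen <- xor(a > 0L, b > 0L)
  keep_degen <- logical(nsite)
  pval <- rep(NA_real_, nsite)
  pval[testable] <- fisher_exact_two_sided(a1[testable], a[testable] - a1[testable],
                                           b1[testable], b[testable] - b1[testable])
  if (degenerate == "binomial" && any(degen)) {
    rate <- sum(rev) / max(1L, sum(ok))
    x <- a1 + b1          # reversals on the site's single populated side
    nn <- a + b
    keep_degen <- degen & x > 0L
    pval[keep_degen] <- stats::pbinom(x[keep_degen] - 1L, nn[keep_degen],
                                      rate, lower.tail = FALSE)
  }

  tested <- testable | keep_degen
  if (!is.null(restrict_to))
    tested <- tested & background$sites %in% restrict_to
  idx <- which(tested)
  if (!length(idx)) {
    out <- data.frame(site_id = character(), direction = character(),
                      p = numeric(), fdr = numeric(), stringsAsFactors = FALSE)
    attr(out, "n_tested") <- 0L
    return(out)
  }
  fdr <- bh_adjust(pval[idx])
  prop_a <- ifelse(a[idx] > 0L, a1[idx] / a[idx], -Inf)
  prop_b <- ifelse(b[idx] > 0L, b1[idx] / b[idx], -Inf)
  direction <- ifelse(prop_a > prop_b, "hyper",
                      ifelse(prop_a < prop_b, "hypo", NA_character_))
  keep <- fdr < fdr_threshold & !is.na(direction)
  out <- data.frame(site_id = background$sites[idx][keep],
                    direction = direction[keep],
                    p = pval[idx][keep], fdr = fdr[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$site_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_tested") <- length(idx)
  out
}

#' Call differential methylation for every sample of a cohort
#'
#' Applies [call_sample_dm()] to each column of `newdata` and stacks the
#' per-sample call tables.
#'
#' @param object an `"rmo_background"`.
#' @param newdata beta matrix (sites x samples) of tumour profiles.
#' @param fdr_threshold,restrict_to,degenerate passed to
#'   [call_sample_dm()].
#' @param ... unused.
#' @return data frame `sample_id`, `site_id`, `direction`, `p`, `fdr`.
#' @export
predict.rmo_background <- function(object, newdata, fdr_threshold = 0.01,
                                   restrict_to = NULL,
                                   degenerate = c("skip", "binomial"), ...) {
  degenerate <- match.arg(degenerate)
  newdata <- as_methyl_matrix(newdata)
  res <- lapply(colnames(newdata), function(s) {
    calls <- call_sample_dm(object, unclass(newdata)[, s], fdr_threshold,
                            restrict_to = restrict_to, degenerate = degenerate)
    if (nrow(calls)) cbind(sample_id = s, calls, stringsAsFactors = FALSE)
    else NULL
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res))
    return(data.frame(sample_id = character(), site_id = character(),
                      direction = character(), p = numeric(), fdr = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
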