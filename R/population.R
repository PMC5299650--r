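#' Population-level differentially methylated sites
#'
#' Per-site two-sample t-test between a cancer and a normal cohort with
#' Benjamini-Hochberg adjustment across all tested sites.  Sites with
#' fewer than two non-missing observations in either group are skipped
#' and reported via `attr(, "skipped")`.  The unequal-variance (Welch)
#' test is the default; `var.equal = TRUE` gives the pooled test.
#'
#' @param cancer,normal beta matrices sharing (a superset of) site ids.
#' @param fdr_threshold BH cutoff below which a site is retained.
#' @param var.equal passed to [stats::t.test()].
#' @return data frame of retained sites: `site_id`, `direction` (`hyper`
#'   when mean cancer beta exceeds mean normal beta), `p`, `fdr`.
#'   Attributes: `n_tested`, `skipped`.
#' @export
ttest_dm <- function(cancer, normal, fdr_threshold = 0.05, var.equal = FALSE) {
  cancer <- as_methyl_matrix(cancer); normal <- as_methyl_matrix(normal)
  sites <- intersect(rownames(cancer), rownames(normal))
  if (!length(sites)) stop("cohorts share no sites")
  sites <- sort(sites)
  nc <- rowSums(!is.na(unclass(cancer)[sites, , drop = FALSE]))
  nn <- rowSums(!is.na(unclass(normal)[sites, , drop = FALSE]))
  skipped <- sites[nc < 2L | nn < 2L]
  tested <- setdiff(sites, skipped)
  if (!length(tested)) stop("no site has >= 2 observations in both groups")
  res <- vapply(tested, function(s) {
    x <- unclass(cancer)[s, ]; y <- unclass(normal)[s, ]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    p <- if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      if (mean(x) == mean(y)) 1 else 0   # constant groups: degenerate t
    } else stats::t.test(x, y, var.equal = var.equal)$p.value
    c(p = p, diff = mean(x) - mean(y))
  }, numeric(2))
  p <- res["p", ]; diff <- res["diff", ]
  fdr <- bh_adjust(p)
  keep <- fdr < fdr_threshold & diff != 0
  out <- data.frame(site_id = tested[keep],
                    direction = ifelse(diff[keep] > 0, "hyper", "hypo"),
                    p = unname(p[keep]), fdr = unname(fdr[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$site_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_tested") <- length(tested)
  attr(out, "skipped") <- skipped
  out
}

#' Stable pairs with significantly frequent reversals in cancer
#'
#' For each stable background pair, samples of each cohort are classified
#' as consistent (ordering matches the stored direction) or reversed
#' (contradicts it); ties and missing members are excluded.  A one-sided
#' Fisher's exact test (hypergeometric upper tail) asks whether reversals
#' are more frequent in the cancer cohort than expected, and BH adjusts
#' across all stable pairs.
#'
#' @param background an `"rmo_background"`.
#' @param cancer,normal beta matrices over the background's site universe.
#' @param fdr_threshold BH cutoff for retention.
#' @param alternative `"greater"` (excess cancer reversals, default) or
#'   `"two.sided"`.
#' @return data frame of retained pairs: `site_i`, `site_j`,
#'   `normal_consistent`, `normal_reversed`, `cancer_consistent`,
#'   `cancer_reversed`, `p`, `fdr`; `attr(, "n_tested")` gives the number
#'   of stable pairs tested.
#' @export
reversal_pair_test <- function(background, cancer, normal,
                               fdr_threshold = 0.05,
                               alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  cancer <- as_methyl_matrix(cancer); normal <- as_methyl_matrix(normal)
  cnt <- function(mat) {
    p <- background$pairs
    m <- unclass(mat)[match(background$sites, rownames(mat)), , drop = FALSE]
    di <- m[p$i, , drop = FALSE] - m[p$j, , drop = FALSE]
    ok <- !is.na(di) & di != 0
    revd <- di > 0                       # reversal if direction is i_less
    grt <- p$direction == "i_greater"
    revd[grt, ] <- di[grt, , drop = FALSE] < 0
    list(consistent = rowSums(ok & !revd), reversed = rowSums(ok & revd))
  }
  cn <- cnt(normal); cc <- cnt(cancer)
  if (all(cc$consistent + cc$reversed == 0))
    stop("cancer cohort has no pairwise-valid samples for any stable pair")
  # one-sided: P(cancer reversals >= observed) conditioning on margins
  p1 <- stats::phyper(cc$reversed - 1,
                      m = cn$reversed + cc$reversed,
                      n = cn$consistent + cc$consistent,
                      k = cc$reversed + cc$consistent, lower.tail = FALSE)
  p <- if (alternative == "greater") p1 else
    fisher_exact_two_sided(cn$consistent, cn$reversed,
                           cc$consistent, cc$reversed)
  fdr <- bh_adjust(p)
  keep <- fdr < fdr_threshold
  pr <- background$pairs[keep, , drop = FALSE]
  out <- data.frame(site_i = background$sites[pr$i],
                    site_j = background$sites[pr$j],
                    normal_consistent = cn$consistent[keep],
                    normal_reversed = cn$reversed[keep],
                    cancer_consistent = cc$consistent[keep],
                    cancer_reversed = cc$reversed[keep],
                    p = p[keep], fdr = fdr[keep], stringsAsFactors = FALSE)
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_tested") <- nrow(background$pairs)
  out
}

#' Sites consistently differentially methylated in two cohort analyses
#'
#' The reproducible population-level DM set: sites retained in both input
#' lists with the same direction, plus the concordance score of the two
#' lists over their shared sites.
#'
#' @param a,b retained-site tables from [ttest_dm()].
#' @return list with `sites` (data frame `site_id`, `direction`) and
#'   `concordance` (an `"rmo_concordance"`).
#' @export
consistent_overlap <- function(a, b) {
  conc <- concordance_score(data.frame(item = a$site_id, direction = a$direction),
                            data.frame(item = b$site_id, direction = b$direction))
  shared <- intersect(a$site_id, b$site_id)
  same <- shared[a$direction[match(shared, a$site_id)] ==
                 b$direction[match(shared, b$site_id)]]
  list(sites = data.frame(site_id = same,
                          direction = a$direction[match(same, a$site_id)],
                          stringsAsFactors = FALSE),
       concordance = conc)
}
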