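#' Concordance of two direction-labelled lists
#'
#' Scores the agreement of two lists of items (stable pairs, DM sites, ...)
#' that each carry a two-valued direction label.  With `k` items shared by
#' the two lists and `s` of them carrying the same direction in both, the
#' concordance score is `s / k`; its chance significance is the upper
#' binomial tail `P(X >= s)` with `X ~ Binomial(k, pe)`, where `pe` is the
#' probability of agreeing by chance (0.5 for two equally likely
#' directions).
#'
#' @param a,b data frames with columns `item` and `direction`.
#' @param pe chance agreement probability.
#' @return object of class `"rmo_concordance"`: list with `k`, `s`,
#'   `score` (`NA` when the lists share nothing), `pe`, `p`.
#' @examples
#' a <- data.frame(item = c("p1", "p2"), direction = c(">", "<"))
#' b <- data.frame(item = c("p1", "p2"), direction = c(">", ">"))
#' concordance_score(a, b)   # k = 2, s = 1, score = 0.5
#' @export
concordance_score <- function(a, b, pe = 0.5) {
  for (d in list(a, b))
    if (!all(c("item", "direction") %in% names(d)))
      stop("lists need columns 'item' and 'direction'")
  if (anyDuplicated(a$item) || anyDuplicated(b$item))
    stop("list items must be unique within each list")
  shared <- intersect(a$item, b$item)
  k <- length(shared)
  if (k == 0L) {
    res <- list(k = 0L, s = 0L, score = NA_real_, pe = pe, p = NA_real_)
  } else {
    da <- a$direction[match(shared, a$item)]
    db <- b$direction[match(shared, b$item)]
    s <- sum(da == db)
    res <- list(k = k, s = s, score = s / k, pe = pe,
                p = binomial_tail_p(k, s, pe))
  }
  class(res) <- "rmo_concordance"
  res
}

#' @export
print.rmo_concordance <- function(x, ...) {
  if (x$k == 0L) {
    cat("concordance: no shared items (k = 0)\n")
  } else {
    cat(sprintf("concordance: s/k = %d/%d = %.4f (pe = %g, binomial p = %.3g)\n",
                x$s, x$k, x$score, x$pe, x$p))
  }
  invisible(x)
}

#' Upper binomial tail for a concordance score
#'
#' `P(X >= s)` for `X ~ Binomial(k, pe)`, i.e.
#' `1 - sum_{i=0}^{s-1} C(k, i) pe^i (1 - pe)^(k - i)`.  Computed through
#' the regularised incomplete beta behind [stats::pbinom()], so it is
#' numerically stable up to very large `k`.
#'
#' @param k number of shared items (trials).
#' @param s number of agreements; `s = 0` gives 1 (empty sum).
#' @param pe chance agreement probability, in (0, 1).
#' @return tail probability in `[0, 1]`.
#' @export
binomial_tail_p <- function(k, s, pe = 0.5) {
  if (any(s > k)) stop("'s' cannot exceed 'k'")
  if (any(s < 0) || any(k < 0)) stop("'k' and 's' must be non-negative")
  if (any(pe <= 0) || any(pe >= 1)) stop("'pe' must lie strictly in (0, 1)")
  stats::pbinom(s - 1, k, pe, lower.tail = FALSE)
}
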