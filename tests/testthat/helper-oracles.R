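# Fixture builders and independent brute-force oracles used across files.

beta_matrix <- function(values, sites = NULL, samples = NULL, group = NULL) {
  m <- matrix(values, nrow = if (is.null(sites)) nrow(values) else length(sites))
  rownames(m) <- sites %||% sprintf("cg%05d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%02d", seq_len(ncol(m)))
  methyl_matrix(m, group = group)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# cohort with a shared underlying ranking plus per-sample noise, so that
# a non-trivial fraction of pairs is stably ordered
structured_beta_matrix <- function(n_sites, n_samples, seed, noise = 0.05,
                                   prefix = "s") {
  set.seed(seed)
  base <- sort(runif(n_sites, 0.05, 0.95))
  m <- sapply(seq_len(n_samples), function(s)
    pmin(pmax(base + rnorm(n_sites, 0, noise), 0), 1))
  dimnames(m) <- list(sprintf("cg%05d", seq_len(n_sites)),
                      sprintf("%s%02d", prefix, seq_len(n_samples)))
  methyl_matrix(m)
}

random_beta_matrix <- function(n_sites, n_samples, seed, na_frac = 0) {
  set.seed(seed)
  m <- matrix(runif(n_sites * n_samples), n_sites,
              dimnames = list(sprintf("cg%05d", seq_len(n_sites)),
                              sprintf("s%02d", seq_len(n_samples))))
  if (na_frac > 0)
    m[sample(length(m), round(na_frac * length(m)))] <- NA
  methyl_matrix(m)
}

# naive triple-loop ordering counter (sites sorted lexicographically)
naive_pair_counts <- function(mat) {
  x <- unclass(mat)[order(rownames(mat)), , drop = FALSE]
  n <- nrow(x)
  out <- list()
  r <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    gt <- lt <- tie <- nv <- 0L
    for (s in seq_len(ncol(x))) {
      xi <- x[i, s]; xj <- x[j, s]
      if (is.na(xi) || is.na(xj)) next
      nv <- nv + 1L
      if (xi > xj) gt <- gt + 1L
      else if (xi < xj) lt <- lt + 1L
      else tie <- tie + 1L
    }
    r <- r + 1L
    out[[r]] <- data.frame(i = i, j = j, n_gt = gt, n_lt = lt,
                           n_tie = tie, n_valid = nv)
  }
  res <- do.call(rbind, out)
  attr(res, "sites") <- rownames(x)
  res
}

# naive stable-pair filter applied directly to naive counts
naive_stable_pairs <- function(mat, theta) {
  cnt <- naive_pair_counts(mat)
  keep <- cnt$n_valid > 0 & pmax(cnt$n_gt, cnt$n_lt) / cnt$n_valid >= theta
  k <- cnt[keep, , drop = FALSE]
  data.frame(i = k$i, j = k$j,
             direction = ifelse(k$n_lt >= k$n_gt, "i_less", "i_greater"),
             stringsAsFactors = FALSE)
}

# exact two-sided Fisher p by full enumeration over margin-fixed tables,
# using only factorial ratios via choose() (independent of dhyper)
enum_fisher_two_sided <- function(x11, x12, x21, x22) {
  r1 <- x11 + x12; r2 <- x21 + x22; c1 <- x11 + x21; N <- r1 + r2
  if (N == 0) return(1)
  xs <- max(0, c1 - r2):min(c1, r1)
  probs <- choose(r1, xs) * choose(r2, c1 - xs) / choose(N, c1)
  obs <- probs[match(x11, xs)]
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

# naive cumulative-binomial upper tail, plain summation
naive_binom_tail <- function(k, s, pe) {
  if (s == 0) return(1)
  1 - sum(choose(k, 0:(s - 1)) * pe^(0:(s - 1)) * (1 - pe)^(k - (0:(s - 1))))
}

# study-condition simulation + the standard evaluation protocol
# (per-sample calls restricted to the population-level DM sites)
run_recovery_study <- function(seed, dm_fraction = 0.1) {
  cfg <- sim_config(dm_fraction = dm_fraction, seed = seed)
  norm <- simulate_normal_cohort(cfg)
  bg <- rmo_background(norm)
  tum <- simulate_tumor_cohort(cfg, norm)
  pop <- ttest_dm(tum$beta, norm, fdr_threshold = 0.05)
  calls <- predict(bg, tum$beta, fdr_threshold = 0.01,
                   restrict_to = pop$site_id)
  list(cfg = cfg, normal = norm, background = bg, tumor = tum,
       population = pop, calls = calls,
       metrics = recovery_metrics(calls, tum$truth))
}
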