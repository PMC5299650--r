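#' Configuration for synthetic methylation cohorts
#'
#' Describes a promoter-like beta-value universe: per-site baseline means
#' `m_i` drawn from a bimodal mixture (a mostly-unmethylated and a
#' mostly-methylated mode, as promoter CpGs show), per-cell beta noise
#' around the baseline with concentration `kappa` (within-site standard
#' deviation `sqrt(m(1-m)/(kappa+1))`, about 0.03 at mid-range for the
#' default `kappa = 300`), and sparse tumour aberrations: a fraction
#' `dm_fraction` of sites is aberrant, each firing in a given tumour with
#' probability `recurrence` and shifting its mean by `delta` in its
#' assigned direction (hyper with probability `frac_hyper`) before noise.
#'
#' @param n_sites,n_normals,n_tumors cohort dimensions.
#' @param dm_fraction fraction of sites carrying an aberration.
#' @param delta mean beta shift of a fired aberration (clipped into
#'   `[1e-6, 1 - 1e-6]`).
#' @param recurrence probability an aberrant site fires in a tumour.
#' @param frac_hyper fraction of aberrant sites shifted upward.
#' @param kappa beta-noise concentration (larger = quieter).
#' @param w_low weight of the low-methylation baseline mode.
#' @param shape_low,shape_high Beta shape pairs of the two baseline modes.
#' @param seed integer seed; mandatory, all randomness flows from it.
#' @return validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_sites = 500L, n_normals = 80L, n_tumors = 30L,
                       dm_fraction = 0.1, delta = 0.3, recurrence = 0.9,
                       frac_hyper = 0.5, kappa = 300,
                       w_low = 0.6, shape_low = c(2, 10),
                       shape_high = c(10, 2), seed) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("'seed' is mandatory")
  cfg <- list(n_sites = as.integer(n_sites), n_normals = as.integer(n_normals),
              n_tumors = as.integer(n_tumors), dm_fraction = dm_fraction,
              delta = delta, recurrence = recurrence, frac_hyper = frac_hyper,
              kappa = kappa, w_low = w_low, shape_low = shape_low,
              shape_high = shape_high, seed = as.integer(seed))
  if (cfg$n_sites < 2L || cfg$n_normals < 2L || cfg$n_tumors < 0L)
    stop("need at least 2 sites and 2 normal samples")
  for (f in c("dm_fraction", "recurrence", "frac_hyper", "w_low"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop("'", f, "' must lie in [0, 1]")
  if (cfg$delta < 0 || cfg$delta > 1) stop("'delta' must lie in [0, 1]")
  if (cfg$kappa <= 0) stop("'kappa' must be positive")
  class(cfg) <- "sim_config"
  cfg
}

# run expr under a temporary RNG state seeded with 'seed'
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

clip01 <- function(m, eps = 1e-6) pmin(pmax(m, eps), 1 - eps)

rbeta_mean <- function(n, m, kappa) {
  m <- clip01(m)
  stats::rbeta(n, m * kappa, (1 - m) * kappa)
}

sim_site_ids <- function(n) sprintf("cg%05d", seq_len(n))

#' Simulate a normal reference cohort
#'
#' Draws per-site baseline means from the configured bimodal mixture,
#' then per-cell beta noise around them.  Site pairs whose baseline means
#' are far apart relative to the noise keep the same within-sample
#' ordering in essentially every sample, reproducing the stable-ordering
#' structure of real normal methylomes.
#'
#' @param config a [sim_config()].
#' @return a [methyl_matrix()] of normals with the baseline means in
#'   `attr(, "baseline")`.
#' @export
simulate_normal_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_sites
    low <- stats::runif(n) < config$w_low
    m <- ifelse(low,
                stats::rbeta(n, config$shape_low[1], config$shape_low[2]),
                stats::rbeta(n, config$shape_high[1], config$shape_high[2]))
    m <- clip01(m)
    vals <- matrix(rbeta_mean(n * config$n_normals, rep(m, config$n_normals),
                              config$kappa),
                   nrow = n,
                   dimnames = list(sim_site_ids(n),
                                   sprintf("N%03d", seq_len(config$n_normals))))
    out <- methyl_matrix(vals, group = "normal")
    attr(out, "baseline") <- stats::setNames(m, sim_site_ids(n))
    out
  })
}

#' Simulate a tumour cohort with recorded ground truth
#'
#' Selects the aberrant-site registry (`dm_fraction` of the universe, each
#' with a fixed direction), then for every tumour lets each registry site
#' fire with probability `recurrence`; a fired site's baseline mean is
#' shifted by `+delta` (hyper) or `-delta` (hypo) before the beta noise is
#' drawn.  The tumour stream is seeded independently of the normal stream
#' (derived from `config$seed`), so the two cohorts share only the
#' baseline.
#'
#' @param config a [sim_config()].
#' @param normal the cohort from [simulate_normal_cohort()] (supplies the
#'   baseline means).
#' @return list of class `"rmo_simulation"`: `beta` (tumour
#'   [methyl_matrix()]), `truth` (data frame `sample_id`, `site_id`,
#'   `direction` of fired aberrations), `registry` (data frame `site_id`,
#'   `direction` of all aberrant sites).
#' @export
simulate_tumor_cohort <- function(config, normal) {
  stopifnot(inherits(config, "sim_config"))
  m <- attr(normal, "baseline")
  if (is.null(m)) stop("'normal' must come from simulate_normal_cohort()")
  n <- config$n_sites
  sites <- sim_site_ids(n)
  with_seed((config$seed + 1013904223L) %% 2147483647L, {
    n_ab <- round(config$dm_fraction * n)
    ab_idx <- sort(sample.int(n, n_ab))
    ab_dir <- ifelse(stats::runif(n_ab) < config$frac_hyper, "hyper", "hypo")
    vals <- matrix(NA_real_, n, config$n_tumors,
                   dimnames = list(sites, sprintf("T%03d", seq_len(config$n_tumors))))
    truth <- vector("list", config$n_tumors)
    for (t in seq_len(config$n_tumors)) {
      mt <- m
      fired <- if (n_ab) stats::runif(n_ab) < config$recurrence else logical(0)
      shift <- ifelse(ab_dir == "hyper", config$delta, -config$delta)
      mt[ab_idx[fired]] <- clip01(m[ab_idx[fired]] + shift[fired])
      vals[, t] <- rbeta_mean(n, mt, config$kappa)
      truth[[t]] <- if (any(fired))
        data.frame(sample_id = colnames(vals)[t],
                   site_id = sites[ab_idx[fired]],
                   direction = ab_dir[fired], stringsAsFactors = FALSE)
      else NULL
    }
    truth <- truth[!vapply(truth, is.null, logical(1))]
    truth <- if (length(truth)) do.call(rbind, truth)
      else data.frame(sample_id = character(), site_id = character(),
                      direction = character(), stringsAsFactors = FALSE)
    rownames(truth) <- NULL
    structure(list(beta = methyl_matrix(vals, group = "tumor"),
                   truth = truth,
                   registry = data.frame(site_id = sites[ab_idx],
                                         direction = ab_dir,
                                         stringsAsFactors = FALSE)),
              class = "rmo_simulation")
  })
}

#' @export
print.rmo_simulation <- function(x, ...) {
  cat(sprintf("simulated tumour cohort: %d sites x %d samples, %d aberrant sites, %d fired aberrations\n",
              nrow(x$beta), ncol(x$beta), nrow(x$registry), nrow(x$truth)))
  invisible(x)
}

#' Precision and recall of calls against injected truth
#'
#' A call is a true positive when the same `(sample_id, site_id)` carries
#' the same direction in the truth table; precision is over all calls,
#' recall over all injected (fired) aberrations.  Both per-sample and
#' pooled figures are returned.
#'
#' @param calls stacked call table (`sample_id`, `site_id`, `direction`).
#' @param truth the `truth` table of an `"rmo_simulation"`.
#' @return list with `pooled` (list `tp`, `n_calls`, `n_truth`,
#'   `precision`, `recall`) and `per_sample` (data frame).
#' @export
recovery_metrics <- function(calls, truth) {
  key <- function(d) paste(d$sample_id, d$site_id, d$direction, sep = "\r")
  tp_flag <- key(calls) %in% key(truth)
  samples <- sort(unique(c(calls$sample_id, truth$sample_id)))
  per <- do.call(rbind, lapply(samples, function(s) {
    nc <- sum(calls$sample_id == s)
    nt <- sum(truth$sample_id == s)
    tp <- sum(tp_flag & calls$sample_id == s)
    data.frame(sample_id = s, tp = tp, n_calls = nc, n_truth = nt,
               precision = if (nc > 0) tp / nc else NA_real_,
               recall = if (nt > 0) tp / nt else NA_real_,
               stringsAsFactors = FALSE)
  }))
  pooled <- list(tp = sum(tp_flag), n_calls = nrow(calls),
                 n_truth = nrow(truth),
                 precision = if (nrow(calls)) sum(tp_flag) / nrow(calls)
                             else NA_real_,
                 recall = if (nrow(truth)) sum(tp_flag) / nrow(truth) else 0)
  list(pooled = pooled, per_sample = per)
}
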