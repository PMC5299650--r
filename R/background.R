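#' Count pairwise beta-value orderings across a cohort
#'
#' For every unordered pair of CpG sites `(i, j)` with `i` before `j` in
#' lexicographic site order, counts the samples where site `i` is strictly
#' greater, strictly lower, or exactly tied with site `j`.  Only samples
#' where both sites are non-missing enter a pair's counts (`n_valid`).
#' Pairs are enumerated in chunks of rows so memory stays bounded; the
#' result is independent of `chunk_size`.
#'
#' @param x beta matrix (sites x samples), at least 2 samples.
#' @param chunk_size number of anchor sites processed per block.
#' @return data frame with integer columns `i`, `j` (indices into the
#'   lexicographically sorted site universe, `i < j`), `n_gt`, `n_lt`,
#'   `n_tie`, `n_valid`, and the sorted site universe in
#'   `attr(, "sites")`.
#' @export
count_pair_orderings <- function(x, chunk_size = 64L) {
  x <- as_methyl_matrix(x)
  if (ncol(x) < 2L) stop("pair-ordering counts need at least 2 samples")
  x <- unclass(x)[order(rownames(x)), , drop = FALSE]
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 sites")
  chunk_size <- max(1L, as.integer(chunk_size))
  out <- vector("list", ceiling((n - 1L) / chunk_size))
  blk <- 0L
  for (start in seq.int(1L, n - 1L, by = chunk_size)) {
    rows <- start:min(start + chunk_size - 1L, n - 1L)
    pieces <- lapply(rows, function(i) {
      xi <- x[i, ]
      rest <- x[(i + 1L):n, , drop = FALSE]
      di <- sweep(rest, 2L, xi)                  # beta_j - beta_i per sample
      ok <- !is.na(di)
      gt <- rowSums(di < 0 & ok)                 # beta_i > beta_j
      lt <- rowSums(di > 0 & ok)
      nv <- rowSums(ok)
      data.frame(i = i, j = (i + 1L):n, n_gt = as.integer(gt),
                 n_lt = as.integer(lt),
                 n_tie = as.integer(nv - gt - lt),
                 n_valid = as.integer(nv))
    })
    blk <- blk + 1L
    out[[blk]] <- do.call(rbind, pieces)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "sites") <- rownames(x)
  attr(res, "n_samples") <- ncol(x)
  res
}

#' Retain pairs whose ordering is conserved across the cohort
#'
#' A pair is stable when one strict direction (`beta_i < beta_j` or
#' `beta_i > beta_j`) holds in at least a fraction `theta` of the samples
#' where both sites were measured.  Ties support neither direction; the
#' denominator is the pair's `n_valid`, so missingness does not penalise a
#' pair.  The default `theta = 0.99` admits a 1% detection error rate.
#'
#' @param counts output of [count_pair_orderings()].
#' @param theta stability threshold in `(0.5, 1]`; retention uses
#'   `support / n_valid >= theta` exactly.
#' @return data frame with columns `i`, `j`, `direction` (`"i_less"` /
#'   `"i_greater"`), `support` (winning count), `n_valid`; site universe
#'   and `theta` carried as attributes.
#' @export
build_stable_pairs <- function(counts, theta = 0.99) {
  if (!is.numeric(theta) || length(theta) != 1L || theta <= 0.5 || theta > 1)
    stop("'theta' must be a single value in (0.5, 1]")
  win <- pmax(counts$n_gt, counts$n_lt)
  keep <- counts$n_valid > 0L & win / counts$n_valid >= theta
  kept <- counts[keep, , drop = FALSE]
  dir <- ifelse(kept$n_lt >= kept$n_gt, "i_less", "i_greater")
  pairs <- data.frame(i = kept$i, j = kept$j, direction = dir,
                      support = pmax(kept$n_gt, kept$n_lt),
                      n_valid = kept$n_valid, stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  attr(pairs, "sites") <- attr(counts, "sites")
  attr(pairs, "theta") <- theta
  pairs
}

#' Per-site stable-pair degrees
#'
#' For each CpG site, `a` counts the stable pairs in which the site is the
#' lower-methylated member and `b` those in which it is the higher member.
#' These are the per-site totals that the individualized caller splits
#' into reversed/consistent cells.
#'
#' @param pairs a stable-pair table from [build_stable_pairs()], with the
#'   site universe in `attr(, "sites")`.
#' @param sites optional site universe overriding the attribute.
#' @return data frame `site_id`, `a`, `b`; `sum(a + b)` equals twice the
#'   number of stable pairs.
#' @export
site_degrees <- function(pairs, sites = attr(pairs, "sites")) {
  if (is.null(sites)) stop("site universe not available; supply 'sites'")
  n <- length(sites)
  less <- pairs$direction == "i_less"
  lo <- as.integer(ifelse(less, pairs$i, pairs$j))
  hi <- as.integer(ifelse(less, pairs$j, pairs$i))
  data.frame(site_id = sites,
             a = tabulate(lo, nbins = n),
             b = tabulate(hi, nbins = n),
             stringsAsFactors = FALSE)
}

#' Fit a stable relative-methylation-ordering background
#'
#' The model underlying individualized differential-methylation calling:
#' from a cohort of normal beta profiles, every site pair whose within-
#' sample ordering is identical in at least `theta` of the samples is
#' recorded with its direction.  The fitted object is the reference that
#' [predict.rmo_background()] tests tumour profiles against.
#'
#' @param x beta matrix of normal samples (sites x samples).
#' @param theta stability threshold, see [build_stable_pairs()].
#' @param chunk_size row-block size for pair counting.
#' @return object of class `"rmo_background"`: list with `pairs`,
#'   `degrees`, `sites`, `n_normals`, `theta`.
#' @seealso [predict.rmo_background()], [save_background()]
#' @examples
#' sim <- simulate_normal_cohort(sim_config(n_sites = 30, n_normals = 20,
#'                                          seed = 1))
#' bg <- rmo_background(sim, theta = 0.99)
#' bg
#' @export
rmo_background <- function(x, theta = 0.99, chunk_size = 64L) {
  counts <- count_pair_orderings(x, chunk_size = chunk_size)
  pairs <- build_stable_pairs(counts, theta = theta)
  deg <- site_degrees(pairs)
  structure(list(pairs = pairs,
                 degrees = deg,
                 sites = attr(counts, "sites"),
                 n_normals = attr(counts, "n_samples"),
                 theta = theta,
                 call = match.call()),
            class = "rmo_background")
}

#' @export
print.rmo_background <- function(x, ...) {
  cat("Stable relative methylation-ordering background\n")
  cat(sprintf("  sites: %d   normal samples: %d   theta: %g\n",
              length(x$sites), x$n_normals, x$theta))
  npair <- choose(length(x$sites), 2)
  cat(sprintf("  stable pairs: %d of %d (%.1f%%)\n",
              nrow(x$pairs), npair, 100 * nrow(x$pairs) / max(1, npair)))
  invisible(x)
}

#' @export
summary.rmo_background <- function(object, ...) {
  deg <- object$degrees$a + object$degrees$b
  out <- list(n_sites = length(object$sites),
              n_normals = object$n_normals,
              theta = object$theta,
              n_stable_pairs = nrow(object$pairs),
              fraction_stable = nrow(object$pairs) /
                max(1, choose(length(object$sites), 2)),
              degree_summary = summary(deg),
              n_isolated_sites = sum(deg == 0L))
  class(out) <- "summary.rmo_background"
  out
}

#' @export
print.summary.rmo_background <- function(x, ...) {
  cat(sprintf("rmo_background: %d sites, %d normals, theta = %g\n",
              x$n_sites, x$n_normals, x$theta))
  cat(sprintf("stable pairs: %d (%.2f%% of all pairs)\n",
              x$n_stable_pairs, 100 * x$fraction_stable))
  cat(sprintf("sites in no stable pair: %d\n", x$n_isolated_sites))
  cat("per-site degree (a + b):\n")
  print(x$degree_summary)
  invisible(x)
}

BACKGROUND_FORMAT <- "rmocomp/background"
BACKGROUND_VERSION <- 1L

#' Persist / restore a fitted background
#'
#' The background is written as a versioned serialized container; loading
#' verifies the format tag and version before returning the object, so a
#' truncated file or a foreign RDS fails loudly rather than yielding a
#' half-usable background.
#'
#' @param object an `"rmo_background"`.
#' @param path file path.
#' @return `load_background()` returns the `"rmo_background"`.
#' @export
save_background <- function(object, path) {
  if (!inherits(object, "rmo_background"))
    stop("'object' must be an rmo_background")
  saveRDS(list(format = BACKGROUND_FORMAT, version = BACKGROUND_VERSION,
               object = object), path)
  invisible(path)
}

#' @rdname save_background
#' @export
load_background <- function(path) {
  payload <- tryCatch(readRDS(path), error = function(e)
    stop("not a readable background container (truncated or not RDS): ",
         path, call. = FALSE))
  if (!is.list(payload) || !identical(payload$format, BACKGROUND_FORMAT))
    stop("file is not an rmocomp background container: ", path)
  if (!identical(payload$version, BACKGROUND_VERSION))
    stop(sprintf("background container version %s not supported (expected %d)",
                 format(payload$version), BACKGROUND_VERSION))
  payload$object
}

#' Export stable pairs as TSV
#'
#' Writes one row per stable pair with resolved site ids, direction and
#' support fraction, for interoperability with other tools.
#'
#' @param object an `"rmo_background"`.
#' @param path file path.
#' @export
export_stable_pairs <- function(object, path) {
  p <- object$pairs
  d <- data.frame(site_i = object$sites[p$i], site_j = object$sites[p$j],
                  direction = p$direction,
                  support = p$support / p$n_valid,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
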