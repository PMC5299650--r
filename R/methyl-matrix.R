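#' Construct a validated beta-value matrix
#'
#' A `methyl_matrix` is a plain numeric matrix of beta values (CpG sites in
#' rows, samples in columns) that has passed validation: unique site and
#' sample identifiers, and every non-missing value inside `[0, 1]`.
#' Missing measurements (e.g. failed detections) are `NA`.  An optional
#' per-sample group label ("normal", "tumor" or "unknown") is carried in
#' the `"group"` attribute.
#'
#' @param values numeric matrix, sites x samples, with row and column names.
#' @param group optional character vector of per-sample labels, one of
#'   `"normal"`, `"tumor"`, `"unknown"`; recycled to `"unknown"` if omitted.
#' @return the validated matrix with class `"methyl_matrix"`.
#' @examples
#' m <- methyl_matrix(matrix(c(0.1, 0.9, 0.4, 0.5), 2,
#'                           dimnames = list(c("cg01", "cg02"), c("s1", "s2"))))
#' @export
methyl_matrix <- function(values, group = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix (sites x samples)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must carry site ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicated site ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicated sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  bad <- which(!is.na(values) & (values < 0 | values > 1))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(values))
    stop(sprintf("beta value out of [0,1] at site %s, sample %s (%g)",
                 rownames(values)[i[1L]], colnames(values)[i[2L]], values[bad[1L]]))
  }
  if (is.null(group)) {
    group <- rep("unknown", ncol(values))
  } else {
    group <- as.character(group)
    if (length(group) == 1L) group <- rep(group, ncol(values))
    if (length(group) != ncol(values))
      stop("'group' must have one label per sample")
    if (!all(group %in% c("normal", "tumor", "unknown")))
      stop("group labels must be 'normal', 'tumor' or 'unknown'")
  }
  names(group) <- colnames(values)
  structure(values, group = group, class = c("methyl_matrix", "matrix", "array"))
}

#' @export
print.methyl_matrix <- function(x, ...) {
  grp <- attr(x, "group")
  cat(sprintf("methyl_matrix: %d CpG sites x %d samples (%s)\n",
              nrow(x), ncol(x),
              paste(sprintf("%d %s", table(grp), names(table(grp))), collapse = ", ")))
  cat(sprintf("missing cells: %d (%.2f%%)\n", sum(is.na(x)),
              100 * mean(is.na(x))))
  invisible(x)
}

#' @export
`[.methyl_matrix` <- function(x, i, j, ..., drop = FALSE) {
  grp <- attr(x, "group")
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    g <- if (missing(j)) grp else grp[j]
    out <- structure(out, group = g, class = c("methyl_matrix", "matrix", "array"))
  }
  out
}

# coerce/validate arbitrary matrix input inside package functions
as_methyl_matrix <- function(x, group = NULL) {
  if (inherits(x, "methyl_matrix") && is.null(group)) return(x)
  methyl_matrix(unclass(x), group = group %||% attr(x, "group"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Beta values from methylated/unmethylated signal intensities
#'
#' Computes the methylation level of each probe as `M / (U + M + 100)`,
#' the standard Illumina beta with an offset of 100 stabilising
#' low-intensity probes.  Values are bounded in `[0, 1)`.
#'
#' @param M,U numeric matrices of methylated / unmethylated signal
#'   intensities with identical dimnames (sites x samples).  `NA` in either
#'   channel yields a missing beta.
#' @param group optional per-sample group labels, see [methyl_matrix()].
#' @return a [methyl_matrix()] of beta values.
#' @export
compute_beta <- function(M, U, group = NULL) {
  if (!identical(dim(M), dim(U)) || !identical(dimnames(M), dimnames(U)))
    stop("'M' and 'U' must have identical dimensions and dimnames")
  neg <- which(!is.na(M) & M < 0 | !is.na(U) & U < 0)
  if (length(neg)) {
    i <- arrayInd(neg[1L], dim(M))
    stop(sprintf("negative signal intensity at site %s, sample %s",
                 rownames(M)[i[1L]], colnames(M)[i[2L]]))
  }
  beta <- M / (U + M + 100)
  methyl_matrix(beta, group = group)
}

#' Read a long-format signal intensity table
#'
#' Expects a tab-delimited file with columns `site_id`, `sample_id`,
#' `M`, `U` (one row per probe per sample) and reshapes it into the two
#' intensity matrices consumed by [compute_beta()].
#'
#' @param path file path.
#' @return list with numeric matrices `M` and `U` (sites x samples).
#' @export
read_signal_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("site_id", "sample_id", "M", "U")
  if (!all(need %in% names(d)))
    stop("signal table must have columns: ", paste(need, collapse = ", "))
  sites <- sort(unique(d$site_id))
  samples <- unique(d$sample_id)
  shape <- function(col) {
    m <- matrix(NA_real_, length(sites), length(samples),
                dimnames = list(sites, samples))
    m[cbind(match(d$site_id, sites), match(d$sample_id, samples))] <- d[[col]]
    m
  }
  list(M = shape("M"), U = shape("U"))
}

#' Sites measured on every input and annotated to all required platforms
#'
#' Returns the CpG sites present in every supplied matrix whose annotation
#' covers all platforms in `platforms` (by default the 27K/450K array
#' intersection the promoter-restricted analysis runs on), in
#' lexicographic order.
#'
#' @param annotation data frame with columns `site_id` and `platforms`
#'   (platform memberships separated by `";"`), as read by
#'   [read_annotation()].
#' @param ... one or more beta matrices whose rownames are site ids.
#' @param platforms character vector of platform labels that must all be
#'   present in a site's membership.
#' @return character vector of site ids, sorted.
#' @export
intersect_common_sites <- function(annotation, ..., platforms = c("27K", "450K")) {
  mats <- list(...)
  memb <- strsplit(annotation$platforms, ";", fixed = TRUE)
  keep <- vapply(memb, function(p) all(platforms %in% p), logical(1))
  sites <- annotation$site_id[keep]
  for (m in mats) sites <- intersect(sites, rownames(m))
  sites <- sort(sites)
  if (!length(sites))
    stop("no CpG site is shared by all inputs and annotated to: ",
         paste(platforms, collapse = ", "))
  sites
}

#' Mask measurements that failed detection
#'
#' Cells whose detection p-value exceeds `threshold` are set to missing;
#' surviving values are untouched.
#'
#' @param x beta matrix (sites x samples).
#' @param detection_p numeric matrix of per-cell detection p-values with
#'   the same dimensions and dimnames as `x`.
#' @param threshold detection p-value cutoff; cells with `p > threshold`
#'   are removed (default 0.05).
#' @return the masked [methyl_matrix()].
#' @export
filter_detection <- function(x, detection_p, threshold = 0.05) {
  x <- as_methyl_matrix(x)
  if (!identical(dim(x), dim(detection_p)) ||
      !identical(dimnames(unclass(x)), dimnames(detection_p)))
    stop("'detection_p' must align with 'x' (same dimensions and dimnames)")
  vals <- unclass(x)
  vals[!is.na(detection_p) & detection_p > threshold] <- NA_real_
  methyl_matrix(vals, group = attr(x, "group"))
}

#' Flag outlying normal samples by minimum pairwise rank correlation
#'
#' For each sample the minimum Spearman correlation against every other
#' sample is computed (pairwise-complete observations); samples whose
#' minimum falls below `flag_threshold` are flagged but never dropped.
#' A flagged normal is a quality-control signal: a reference profile that
#' ranks sites very differently from the rest of the cohort.
#'
#' @param x beta matrix of normal samples (>= 3 columns).
#' @param flag_threshold correlation below which a sample is flagged.
#' @return data frame with `sample_id`, `min_correlation`, `flagged`.
#' @export
qc_normal_correlation <- function(x, flag_threshold = 0.72) {
  x <- as_methyl_matrix(x)
  if (ncol(x) < 3L) stop("need at least 3 samples for cohort QC")
  cc <- stats::cor(unclass(x), method = "spearman", use = "pairwise.complete.obs")
  diag(cc) <- NA
  mins <- apply(cc, 2L, min, na.rm = TRUE)
  data.frame(sample_id = colnames(x),
             min_correlation = unname(mins),
             flagged = unname(mins) < flag_threshold,
             stringsAsFactors = FALSE)
}

#' Read / write a beta-value matrix as TSV
#'
#' Tab-delimited layout: header row of sample ids, first column of site
#' ids, `NA` for missing cells.  The round trip
#' `read_methyl_matrix(write_methyl_matrix(m, f))` preserves ids, values
#' and missingness.
#'
#' @param path file path.
#' @param group optional per-sample labels attached on read.
#' @return a [methyl_matrix()].
#' @export
read_methyl_matrix <- function(path, group = NULL) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  nfld <- lengths(fields)
  bad <- which(nfld[-1L] != length(header)) + 1L
  if (length(bad))
    stop(sprintf("ragged row at line %d of %s: %d fields, expected %d",
                 bad[1L], path, nfld[bad[1L]], length(header)))
  samples <- header[-1L]
  sites <- vapply(fields[-1L], `[`, character(1), 1L)
  dup <- sites[duplicated(sites)]
  if (length(dup))
    stop("duplicated site id in ", path, ": ", paste(unique(dup), collapse = ", "))
  body <- fields[-1L]
  vals <- matrix(NA_real_, length(sites), length(samples),
                 dimnames = list(sites, samples))
  for (r in seq_along(body)) {
    cell <- body[[r]][-1L]
    miss <- cell %in% c("NA", "")
    num <- suppressWarnings(as.numeric(cell))
    badc <- which(!miss & is.na(num))
    if (length(badc))
      stop(sprintf("non-numeric cell '%s' at line %d, column %d of %s",
                   cell[badc[1L]], r + 1L, badc[1L] + 1L, path))
    vals[r, ] <- num
  }
  methyl_matrix(vals, group = group)
}

#' @rdname read_methyl_matrix
#' @param x beta matrix to write.
#' @export
write_methyl_matrix <- function(x, path) {
  x <- as_methyl_matrix(x)
  d <- data.frame(site_id = rownames(x), unclass(x),
                  check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a CpG site annotation table
#'
#' Tab-delimited with columns `site_id`, `gene_symbol`, `promoter_flag`
#' (logical), `platforms` (`";"`-separated platform labels).  Several rows
#' may share a site id when a site maps to several genes.
#'
#' @param path file path.
#' @return data frame with those columns.
#' @export
read_annotation <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("site_id", "gene_symbol", "promoter_flag", "platforms")
  if (!all(need %in% names(d)))
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  d$promoter_flag <- as.logical(d$promoter_flag)
  d
}
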