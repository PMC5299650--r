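#' Precision of one sample's calls against its paired adjacent normal
#'
#' Scores individualized calls with the paired adjacent normal tissue as
#' the gold standard: a call is a true positive when its direction matches
#' the sign of `tumour beta - paired normal beta` at that site.  A zero
#' observed difference contradicts any call and counts as a false
#' positive; sites missing in either profile are excluded from both
#' counts (and reported).  Precision is the positive predictive value
#' `TP / (TP + FP)`.
#'
#' @param calls call table for one sample (columns `site_id`,
#'   `direction`).
#' @param tumor_beta,normal_beta named beta vectors for the pair.
#' @param restrict_to optional site set calls are restricted to before
#'   scoring (e.g. the population-level DM sites).
#' @return list `tp`, `fp`, `excluded`, `precision` (`NA` when no call
#'   survives).
#' @export
precision_against_paired <- function(calls, tumor_beta, normal_beta,
                                     restrict_to = NULL) {
  if (!is.null(restrict_to))
    calls <- calls[calls$site_id %in% restrict_to, , drop = FALSE]
  tb <- tumor_beta[match(calls$site_id, names(tumor_beta))]
  nb <- normal_beta[match(calls$site_id, names(normal_beta))]
  valid <- !is.na(tb) & !is.na(nb)
  d <- tb[valid] - nb[valid]
  dir <- calls$direction[valid]
  tp <- sum((dir == "hyper" & d > 0) | (dir == "hypo" & d < 0))
  fp <- sum(valid) - tp
  list(tp = tp, fp = fp, excluded = sum(!valid),
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_)
}

#' Per-site aberration recurrence across a cohort
#'
#' Frequencies with which each site is called hyper- or hypomethylated
#' over the cohort's samples, and the subset whose larger frequency
#' strictly exceeds `min_frequency` (the recurrent aberrations).
#'
#' @param calls stacked call table (columns `sample_id`, `site_id`,
#'   `direction`), e.g. from [predict.rmo_background()].
#' @param n_samples cohort size the frequencies are relative to.
#' @param min_frequency recurrence cutoff; retention uses a strict `>`.
#' @return list with `frequencies` (data frame `site_id`,
#'   `hyper_frequency`, `hypo_frequency`, `n_samples`) and `recurrent`
#'   (the high-frequency subset with a `direction` column).
#' @export
aberration_frequency <- function(calls, n_samples, min_frequency = 0.9) {
  sites <- sort(unique(calls$site_id))
  hyper <- table(factor(calls$site_id[calls$direction == "hyper"], levels = sites))
  hypo <- table(factor(calls$site_id[calls$direction == "hypo"], levels = sites))
  freq <- data.frame(site_id = sites,
                     hyper_frequency = as.vector(hyper) / n_samples,
                     hypo_frequency = as.vector(hypo) / n_samples,
                     n_samples = n_samples, stringsAsFactors = FALSE)
  top <- pmax(freq$hyper_frequency, freq$hypo_frequency)
  rec <- freq[top > min_frequency, , drop = FALSE]
  rec$direction <- ifelse(rec$hyper_frequency >= rec$hypo_frequency,
                          "hyper", "hypo")
  rownames(freq) <- rownames(rec) <- NULL
  list(frequencies = freq, recurrent = rec)
}

#' Direction frequency of a site over paired tumour/normal profiles
#'
#' Over sample pairs where the site is measured in both members, the
#' fraction with strictly higher and strictly lower tumour beta; ties
#' count toward neither.
#'
#' @param site_id one site id.
#' @param tumor,normal beta matrices with pair-matched columns (column
#'   `k` of each belongs to the same patient).
#' @return list `n_pairs` (valid pairs), `frac_higher`, `frac_lower`
#'   (both `NA` when no pair is valid).
#' @export
paired_direction_frequency <- function(site_id, tumor, normal) {
  if (ncol(tumor) != ncol(normal)) stop("cohorts must be pair-matched")
  tb <- unclass(as_methyl_matrix(tumor))[match(site_id, rownames(tumor)), ]
  nb <- unclass(as_methyl_matrix(normal))[match(site_id, rownames(normal)), ]
  ok <- !is.na(tb) & !is.na(nb)
  if (!any(ok))
    return(list(n_pairs = 0L, frac_higher = NA_real_, frac_lower = NA_real_))
  list(n_pairs = sum(ok),
       frac_higher = sum(tb[ok] > nb[ok]) / sum(ok),
       frac_lower = sum(tb[ok] < nb[ok]) / sum(ok))
}

#' Promoter hypermethylation status of genes in one sample
#'
#' A gene is hypermethylated in a sample when at least one CpG site in its
#' promoter is called hypermethylated and none is called hypomethylated.
#' Genes with no annotated promoter CpG are absent from the output.
#'
#' @param calls call table for one sample (`site_id`, `direction`).
#' @param annotation annotation table (see [read_annotation()]); only rows
#'   with `promoter_flag` are used.
#' @return data frame `gene_symbol`, `status` (`"hypermethylated"` /
#'   `"not"`), `n_promoter_sites`.
#' @export
gene_methylation_status <- function(calls, annotation) {
  ann <- annotation[annotation$promoter_flag, , drop = FALSE]
  genes <- sort(unique(ann$gene_symbol))
  status <- vapply(genes, function(g) {
    sites <- ann$site_id[ann$gene_symbol == g]
    dirs <- calls$direction[calls$site_id %in% sites]
    if (any(dirs == "hyper") && !any(dirs == "hypo")) "hypermethylated" else "not"
  }, character(1))
  nsit <- vapply(genes, function(g) sum(ann$gene_symbol == g), integer(1))
  data.frame(gene_symbol = genes, status = unname(status),
             n_promoter_sites = unname(nsit), stringsAsFactors = FALSE)
}

#' Down-regulation frequency of a gene over paired expression profiles
#'
#' Fraction of patient pairs whose tumour expression is strictly lower
#' than the paired normal expression; an exact tie counts as not
#' down-regulated.
#'
#' @param tumor_expr,normal_expr numeric vectors of pair-matched
#'   expression values for one gene.
#' @return list `n_pairs`, `frac_down`.
#' @export
downregulation_frequency <- function(tumor_expr, normal_expr) {
  if (length(tumor_expr) != length(normal_expr))
    stop("expression vectors must be pair-matched")
  ok <- !is.na(tumor_expr) & !is.na(normal_expr)
  if (!any(ok)) return(list(n_pairs = 0L, frac_down = NA_real_))
  list(n_pairs = sum(ok),
       frac_down = sum(tumor_expr[ok] < normal_expr[ok]) / sum(ok))
}

#' Pathway over-representation for one sample's gene list
#'
#' One-sided hypergeometric test per pathway (classic over-representation
#' analysis): the probability of drawing at least the observed overlap
#' when `length(genes)` genes are sampled from the universe, BH-adjusted
#' across pathways.  Pathway membership is intersected with the universe
#' first.
#'
#' @param genes character vector (e.g. a sample's hypermethylated genes).
#' @param pathways named list of gene sets, e.g. from [read_gmt()].
#' @param universe all genes the list could have been drawn from (the
#'   annotated platform genes).
#' @param fdr_threshold cutoff for the `significant` column.
#' @return data frame `pathway_id`, `pathway_size`, `overlap`, `p`,
#'   `fdr`, `significant`; zero rows for an empty gene list.
#' @export
pathway_enrichment <- function(genes, pathways, universe, fdr_threshold = 0.05) {
  genes <- intersect(unique(genes), universe)
  if (!length(genes) || !length(pathways))
    return(data.frame(pathway_id = character(), pathway_size = integer(),
                      overlap = integer(), p = numeric(), fdr = numeric(),
                      significant = logical(), stringsAsFactors = FALSE))
  sizes <- vapply(pathways, function(g) length(intersect(g, universe)), integer(1))
  overlap <- vapply(pathways, function(g) length(intersect(g, genes)), integer(1))
  N <- length(unique(universe))
  p <- stats::phyper(overlap - 1, sizes, N - sizes, length(genes),
                     lower.tail = FALSE)
  fdr <- bh_adjust(p)
  out <- data.frame(pathway_id = names(pathways), pathway_size = sizes,
                    overlap = overlap, p = p, fdr = fdr,
                    significant = fdr < fdr_threshold,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read gene sets in GMT format
#'
#' One pathway per line: id, description, then member genes, all
#' tab-separated.
#'
#' @param path file path.
#' @return named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop(sprintf("malformed GMT line %d: fewer than 3 fields", short[1L]))
  stats::setNames(lapply(fields, function(f) unique(f[-(1:2)])),
                  vapply(fields, `[`, character(1), 1L))
}
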