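## Per-cohort expression distributions for a single gene, on the analysis
## scale log2(intensity + 1): binned frequency vectors that can be clustered
## (Ward.D2 on Euclidean distance) to group cancer types by the shape of
## their expression distribution, plus the "high-expressor fraction"
## statistic: the share of a cohort's samples above the mean expression of a
## reference cohort, with cohorts above 5% flagged.

#' Analysis scale for cohort distributions
#'
#' @param x nonnegative linear-scale intensities.
#' @return `log2(x + 1)`.
#' @export
log2_intensity <- function(x) log2(x + 1)

#' Default shared bin edges
#'
#' Equal-width bins spanning the pooled central range of the analysis-scale
#' values (0.5th to 99.5th percentile by default), so all cohorts are binned
#' on a common grid.
#'
#' @param pooled numeric vector: analysis-scale values pooled over cohorts.
#' @param n_bins number of bins.
#' @param probs lower/upper quantile of the pooled range to span.
#' @return ascending numeric vector of `n_bins + 1` edges.
#' @export
default_bin_edges <- function(pooled, n_bins = 64, probs = c(0.005, 0.995)) {
  stopifnot(length(pooled) > 0L, n_bins >= 1L)
  rng <- stats::quantile(pooled, probs = probs, names = FALSE)
  if (rng[[1L]] == rng[[2L]]) rng <- rng + c(-0.5, 0.5)
  seq(rng[[1L]], rng[[2L]], length.out = n_bins + 1L)
}

#' Build one cohort's binned expression distribution
#'
#' Histogram frequencies on shared bin edges; values outside the edges are
#' clipped into the terminal bins and counted, so frequencies always sum
#' to 1.
#'
#' @param values per-sample analysis-scale expression of one gene (non-empty).
#' @param bin_edges ascending numeric vector of edges shared across cohorts.
#' @param cohort cohort label.
#' @return object of class `"cohort_distribution"`: list with `cohort`,
#'   `bin_edges`, `freqs` (sums to 1), `n`, `n_clipped`.
#' @export
build_distribution <- function(values, bin_edges, cohort = "cohort") {
  if (length(values) == 0L) stop("empty cohort '", cohort, "'")
  if (is.unsorted(bin_edges, strictly = TRUE))
    stop("bin_edges must be strictly ascending")
  lo <- bin_edges[[1L]]; hi <- bin_edges[[length(bin_edges)]]
  n_clipped <- sum(values < lo | values > hi)
  clipped <- pmin(pmax(values, lo), hi)
  counts <- graphics::hist(clipped, breaks = bin_edges, plot = FALSE,
                 include.lowest = TRUE, right = TRUE)$counts
  structure(list(cohort = cohort, bin_edges = bin_edges,
                 freqs = counts / length(values), n = length(values),
                 n_clipped = n_clipped),
            class = "cohort_distribution")
}

#' Cluster cohort distributions (Ward.D2)
#'
#' Agglomerative clustering of the frequency vectors with Ward.D2 linkage on
#' Euclidean distance. Cohorts are sorted by label before clustering, so the
#' result is invariant to input order with a deterministic label tie-break.
#'
#' @param dists list of [build_distribution()] results sharing identical
#'   `bin_edges`.
#' @return an [stats::hclust] object (merge list, heights, leaf order);
#'   labels are cohort names.
#' @export
cluster_distributions <- function(dists) {
  if (length(dists) < 2L) stop("need >= 2 cohorts to cluster")
  edges <- lapply(dists, `[[`, "bin_edges")
  if (!all(vapply(edges[-1L], identical, logical(1L), edges[[1L]])))
    stop("all cohorts must share identical bin_edges")
  labs <- vapply(dists, `[[`, character(1L), "cohort")
  if (anyDuplicated(labs)) stop("duplicate cohort labels")
  ord <- order(labs)
  freq <- do.call(rbind, lapply(dists[ord], `[[`, "freqs"))
  rownames(freq) <- labs[ord]
  stats::hclust(stats::dist(freq, method = "euclidean"), method = "ward.D2")
}

#' High-expressor fraction
#'
#' Fraction of a cohort's samples whose expression exceeds the arithmetic
#' mean of a reference cohort (both on the same analysis scale). Cohorts with
#' fraction strictly greater than `flag_above` (5% by default) are flagged as
#' high-expressor cohorts.
#'
#' @param cohort_values non-empty numeric vector.
#' @param reference_values non-empty numeric vector defining the threshold.
#' @param flag_above flag cutoff on the fraction (strict `>`).
#' @return list with `fraction`, `threshold`, `is_high_cohort`.
#' @export
high_fraction <- function(cohort_values, reference_values,
                          flag_above = 0.05) {
  if (length(cohort_values) == 0L || length(reference_values) == 0L)
    stop("cohort and reference values must be non-empty")
  thr <- mean(reference_values)
  frac <- mean(cohort_values > thr)
  list(fraction = frac, threshold = thr,
       is_high_cohort = frac > flag_above)
}
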