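## Correlation screens: signature scores (mean squared expression over the
## signature's genes), Pearson correlation with t-based two-sided p-values,
## two-stage adaptive FDR (Benjamini-Krieger-Yekutieli), and the
## significance-calling logic shared by the immune-signature screen
## (q < alpha AND |r| > r_min) and the PAS-vs-driver association
## (q < alpha only, by default).

#' Read a plain GMT file of gene signatures
#'
#' `name<TAB>description<TAB>gene<TAB>gene...`; descriptions are dropped.
#'
#' @param path file path.
#' @return named list of character gene vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0L)
    stop("line ", short[[1L]], " of ", path,
         ": expected name, description and >= 1 gene")
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, character(1L), 1L)
  if (anyDuplicated(names(sets)))
    stop("duplicate signature name in ", path)
  sets
}

#' Signature score per sample
#'
#' The mean squared expression over the signature's measured genes:
#' `score(s) = mean_g expr[g, s]^2`. A root-mean-square variant is available
#' as an option.
#'
#' @param expr numeric matrix, genes x samples.
#' @param genes character vector: the signature's gene list.
#' @param method `"mean_square"` (default) or `"rms"` (square root of the
#'   mean square).
#' @return named numeric vector of per-sample scores; attribute `n_missing`
#'   counts signature genes absent from `expr`.
#' @export
signature_score <- function(expr, genes, method = c("mean_square", "rms")) {
  method <- match.arg(method)
  measured <- intersect(genes, rownames(expr))
  if (length(measured) == 0L)
    stop("no signature gene measured (signature genes: ",
         paste(utils::head(genes, 5L), collapse = ", "), ")")
  sc <- colMeans(expr[measured, , drop = FALSE]^2)
  if (method == "rms") sc <- sqrt(sc)
  attr(sc, "n_missing") <- length(genes) - length(measured)
  sc
}

#' Pearson correlation with two-sided p-value
#'
#' Pairwise-complete Pearson correlation; the p-value comes from the t
#' transform `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of
#' freedom (via [stats::cor.test()]). A constant vector has no defined
#' correlation and signals a classed error (`paslab_constant`).
#'
#' @param x,y numeric vectors of equal length.
#' @return list with `r`, `p`, `n` (complete pairs used).
#' @export
pearson_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L)
    stop("need >= 3 complete observation pairs (got ", length(x), ")")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    cond <- structure(
      class = c("paslab_constant", "error", "condition"),
      list(message = "undefined correlation: constant vector",
           call = sys.call(-1L)))
    stop(cond)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Two-stage adaptive FDR (Benjamini-Krieger-Yekutieli)
#'
#' The two-stage linear step-up procedure: stage 1 runs Benjamini-Hochberg at
#' the reduced level `alpha' = alpha / (1 + alpha)` and uses the rejection
#' count r1 to estimate the number of true nulls `m0 = m - r1`; stage 2
#' re-runs the step-up at level `alpha' * m / m0` (all hypotheses are
#' rejected if `m0 = 0`). Reported q-values are the stage-2 step-up q-values
#' rescaled by `(1 + alpha) * m0 / m` so that `q <= alpha` is exactly the
#' rejection rule.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @param alpha target FDR level.
#' @return list with `q` (same length/order as `pvals`), `reject` (logical),
#'   `m0` (estimated number of true nulls). Empty input gives empty output.
#' @export
fdr_twostage <- function(pvals, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  m <- length(pvals)
  if (m == 0L)
    return(list(q = numeric(0L), reject = logical(0L), m0 = 0L))
  if (any(is.na(pvals)) || any(pvals < 0) || any(pvals > 1))
    stop("p-values must lie in [0, 1] with no missing values")
  bh_q <- function(p) {  # step-up q-values: monotone min of p * m / rank
    o <- order(p, decreasing = TRUE)
    ro <- order(o)
    pmin(1, cummin(p[o] * m / (m - seq_along(p) + 1L)))[ro]
  }
  q1 <- bh_q(pvals)
  alpha_p <- alpha / (1 + alpha)
  r1 <- sum(q1 <= alpha_p)
  m0 <- m - r1
  if (m0 == 0L)
    return(list(q = rep(0, m), reject = rep(TRUE, m), m0 = 0L))
  q <- pmin(1, q1 * (m0 / m) * (1 + alpha))
  list(q = q, reject = q <= alpha, m0 = m0)
}

#' Correlation screen of features against a driver gene
#'
#' Correlates each feature's per-sample score with the driver's per-sample
#' expression, within cohorts, applies two-stage FDR across features within
#' each cohort (the declared correction family), and calls significance as
#' `q < alpha` and `|r| > r_min`. Features with an undefined (constant)
#' correlation are excluded and logged.
#'
#' @param driver named numeric vector: per-sample driver values.
#' @param scores numeric matrix, features x samples (shared sample names).
#' @param cohorts optional named character vector sample -> cohort label; a
#'   single cohort `"all"` is assumed when omitted.
#' @param alpha FDR level.
#' @param r_min minimum absolute correlation for significance (strict `>`).
#' @return list with `records` (data.frame: feature, cohort, r, p, q,
#'   significant, n), `counts` (data.frame per cohort: n_pos_sig,
#'   n_neg_sig), `dropped` (features with undefined correlation).
#' @export
correlation_screen <- function(driver, scores, cohorts = NULL, alpha = 0.05,
                               r_min = 0.2) {
  stopifnot(alpha > 0, alpha < 1, r_min >= 0)
  if (is.null(names(driver))) stop("driver must be a named vector")
  if (is.null(colnames(scores))) stop("scores must have sample colnames")
  samples <- intersect(names(driver), colnames(scores))
  if (length(samples) < 3L) stop("driver and scores share < 3 samples")
  if (is.null(cohorts)) cohorts <- stats::setNames(rep("all", length(samples)),
                                            samples)
  recs <- list(); dropped <- character(0L)
  for (co in sort(unique(cohorts[samples]))) {
    ss <- samples[cohorts[samples] == co]
    if (length(ss) < 3L) next
    rows <- lapply(rownames(scores), function(f) {
      tryCatch({
        pt <- pearson_test(driver[ss], scores[f, ss])
        data.frame(feature = f, cohort = co, r = pt$r, p = pt$p,
                   n = pt$n, stringsAsFactors = FALSE)
      }, paslab_constant = function(e) {
        dropped <<- c(dropped, paste0(f, "@", co)); NULL
      }, error = function(e) {
        dropped <<- c(dropped, paste0(f, "@", co)); NULL
      })
    })
    rows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
    if (is.null(rows) || nrow(rows) == 0L) next
    fdr <- fdr_twostage(rows$p, alpha = alpha)
    rows$q <- fdr$q
    rows$significant <- fdr$reject & rows$q < alpha & abs(rows$r) > r_min
    recs[[co]] <- rows
  }
  records <- do.call(rbind, recs)
  if (is.null(records) || nrow(records) == 0L)
    stop("no feature yielded a defined correlation")
  rownames(records) <- NULL
  counts <- do.call(rbind, lapply(split(records, records$cohort),
    function(d) data.frame(cohort = d$cohort[[1L]],
                           n_pos_sig = sum(d$significant & d$r > 0),
                           n_neg_sig = sum(d$significant & d$r < 0),
                           stringsAsFactors = FALSE)))
  rownames(counts) <- NULL
  if (length(dropped) > 0L)
    message(length(dropped),
            " feature/cohort pair(s) dropped (undefined correlation)")
  list(records = records, counts = counts, dropped = dropped)
}

#' Pathway-activation versus driver association
#'
#' Correlates each pathway's per-sample PAL with the driver gene's
#' expression across one cohort of samples and applies two-stage FDR across
#' pathways. By default significance requires only `q < alpha` (no
#' effect-size cutoff).
#'
#' @param pas numeric matrix, samples x pathways (from [per_sample_pas()]).
#' @param driver named numeric vector of per-sample driver values.
#' @param alpha FDR level.
#' @param r_min optional minimum |r| (default 0).
#' @return list with `records` (feature = pathway id) and `n_significant`.
#' @export
pas_association <- function(pas, driver, alpha = 0.05, r_min = 0) {
  if (is.null(rownames(pas))) stop("pas must have sample rownames")
  samples <- intersect(names(driver), rownames(pas))
  if (length(samples) < 3L) stop("driver and pas share < 3 samples")
  if (stats::sd(driver[samples]) == 0) stop("driver is constant")
  scr <- correlation_screen(driver[samples],
                            t(pas[samples, , drop = FALSE]),
                            alpha = alpha, r_min = r_min)
  list(records = scr$records, n_significant = sum(scr$records$significant))
}
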