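## Pathway activation level (PAL, also reported as pathway activation
## strength, PAS):
##
##   PAL(p) = sum_n NII(n,p) * ARR(n,p) * log(CNR_n)
##            ------------------------------------------
##            sum_n NII(n,p) * |ARR(n,p)|
##
## where CNR_n is the gene's case-to-normal ratio (case mean over control
## mean), NII is pathway membership (the sum runs over measured member
## genes), and ARR is the signed activator/repressor role. The denominator
## normalizes by total absolute role weight so PAL is comparable across
## pathways of different sizes. PAL > 0: pathway activated in the case group;
## PAL < 0: suppressed.

#' Case-to-normal ratios
#'
#' Per gene, the ratio of the mean expression across case samples to the mean
#' across control samples. Means are arithmetic by default; geometric means
#' are available as an option. Both numerator and denominator are floored at
#' `eps` before division and floored genes are recorded.
#'
#' @param case numeric matrix (genes x case samples) or named vector.
#' @param control numeric matrix (genes x control samples) or named vector,
#'   same gene index as `case`.
#' @param eps positive flooring constant.
#' @param norm_mode `"control_arith_mean"` (default) or
#'   `"control_geom_mean"`: how per-gene means are taken on both sides.
#' @return object of class `"cnr"`: list with `cnr` (named positive vector),
#'   `norm_mode`, `floored_genes`.
#' @export
compute_cnr <- function(case, control, eps = 1e-8,
                        norm_mode = c("control_arith_mean",
                                      "control_geom_mean")) {
  norm_mode <- match.arg(norm_mode)
  stopifnot(eps > 0)
  as_mat <- function(x) {
    if (is.matrix(x)) x else matrix(x, ncol = 1L,
                                    dimnames = list(names(x), "s1"))
  }
  case <- as_mat(case); control <- as_mat(control)
  if (ncol(case) == 0L || ncol(control) == 0L)
    stop("case and control must each contain >= 1 sample")
  if (is.null(rownames(case)) || is.null(rownames(control)))
    stop("case and control need gene rownames")
  genes <- intersect(rownames(case), rownames(control))
  if (length(genes) == 0L)
    stop("case and control share no genes")
  case <- case[genes, , drop = FALSE]
  control <- control[genes, , drop = FALSE]
  mfun <- if (norm_mode == "control_geom_mean") {
    function(m) exp(rowMeans(log(pmax(m, eps))))
  } else {
    rowMeans
  }
  num <- mfun(case); den <- mfun(control)
  floored <- genes[num < eps | den < eps]
  cnr <- pmax(num, eps) / pmax(den, eps)
  names(cnr) <- genes
  structure(list(cnr = cnr, norm_mode = norm_mode, floored_genes = floored),
            class = "cnr")
}

#' Pathway activation level for one pathway
#'
#' Evaluates the role-weighted log-ratio average over the pathway members
#' measured in `cnr`. Members with ARR = 0 contribute to neither numerator
#' nor denominator; unmeasured members are excluded from both (they carry no
#' evidence and must not dilute the normalizer). If every measured member is
#' neutral the pathway is unscorable and a classed error
#' (`paslab_unscorable`) is signalled.
#'
#' @param cnr a `"cnr"` object from [compute_cnr()] (or a named positive
#'   vector of ratios).
#' @param p a [pathway()].
#' @param log_base logarithm base (> 1); base 10 by default, so a planted
#'   ten-fold coherent shift of activator members yields PAL = 1.
#' @return a single finite numeric; attribute `n_members_used` counts the
#'   measured members entering the score (including neutral ones).
#' @export
compute_pal <- function(cnr, p, log_base = 10) {
  stopifnot(inherits(p, "pathway"), log_base > 1)
  v <- if (inherits(cnr, "cnr")) cnr$cnr else cnr
  if (is.null(names(v))) stop("cnr must be a named vector of ratios")
  p <- restrict_to_measured(p, names(v))  # may signal paslab_unmeasured
  arr <- p$members
  denom <- sum(abs(arr))
  if (denom == 0) {
    cond <- structure(
      class = c("paslab_unscorable", "error", "condition"),
      list(message = paste0("pathway '", p$id,
                            "' unscorable: all measured members neutral"),
           call = sys.call(-1L)))
    stop(cond)
  }
  lcnr <- log(v[names(arr)], base = log_base)
  pal <- sum(arr * lcnr) / denom
  attr(pal, "n_members_used") <- length(arr)
  pal
}

#' Batch PAL over a pathway collection
#'
#' Computes one case-vs-control PAL per scorable pathway; pathways with no
#' measured member or only neutral measured members are listed with a status
#' instead of a score.
#'
#' @param expr numeric matrix, genes x samples.
#' @param design data.frame with columns `sample` and `group`
#'   (`case`/`control`; other labels ignored).
#' @param coll a [pathway_collection()].
#' @param log_base,eps,norm_mode passed to [compute_cnr()]/[compute_pal()].
#' @return data.frame with columns `pathway`, `class`, `pal`,
#'   `n_members_used`, `status` (`"scored"`, `"unmeasured"`,
#'   `"unscorable"`); `pal` is `NA` for unscored rows. The `"cnr"` object is
#'   attached as attribute `cnr`.
#' @export
pas_table <- function(expr, design, coll, log_base = 10, eps = 1e-8,
                      norm_mode = "control_arith_mean") {
  validate_expression(expr)
  stopifnot(inherits(coll, "pathway_collection"))
  if (!all(c("sample", "group") %in% colnames(design)))
    stop("design needs columns (sample, group)")
  cs <- design$sample[design$group == "case"]
  ns <- design$sample[design$group == "control"]
  if (length(cs) == 0L || length(ns) == 0L)
    stop("design must name >= 1 case and >= 1 control sample")
  missing <- setdiff(c(cs, ns), colnames(expr))
  if (length(missing) > 0L)
    stop("design samples absent from expression matrix: ",
         paste(missing, collapse = ", "))
  cnr <- compute_cnr(expr[, cs, drop = FALSE], expr[, ns, drop = FALSE],
                     eps = eps, norm_mode = norm_mode)
  out <- do.call(rbind, lapply(coll$pathways, function(p) {
    res <- tryCatch(
      {
        pal <- compute_pal(cnr, p, log_base = log_base)
        data.frame(pathway = p$id, class = p$klass, pal = as.numeric(pal),
                   n_members_used = attr(pal, "n_members_used"),
                   status = "scored", stringsAsFactors = FALSE)
      },
      paslab_unmeasured = function(e)
        data.frame(pathway = p$id, class = p$klass, pal = NA_real_,
                   n_members_used = 0L, status = "unmeasured",
                   stringsAsFactors = FALSE),
      paslab_unscorable = function(e)
        data.frame(pathway = p$id, class = p$klass, pal = NA_real_,
                   n_members_used = 0L, status = "unscorable",
                   stringsAsFactors = FALSE))
    res
  }))
  rownames(out) <- NULL
  attr(out, "cnr") <- cnr
  attr(out, "context") <- list(n_case = length(cs), n_control = length(ns),
                               log_base = log_base, norm_mode = norm_mode)
  out
}

#' Per-sample PAL table
#'
#' Scores each sample alone as "case" against a norm: either the cohort mean
#' profile (default; every sample contributes to the norm) or an explicit
#' control sample set. This is the per-tumor PAS used when correlating
#' pathway activity with a driver gene across a cohort.
#'
#' @param expr numeric matrix, genes x samples.
#' @param coll a [pathway_collection()].
#' @param norm `"cohort_mean"` or `"control_set"`.
#' @param control_samples sample ids (required for `norm = "control_set"`).
#' @param log_base,eps,norm_mode as in [pas_table()].
#' @return numeric matrix, samples x scorable pathways; skipped pathways are
#'   recorded in attribute `skipped` (data.frame pathway, status).
#' @export
per_sample_pas <- function(expr, coll, norm = c("cohort_mean", "control_set"),
                           control_samples = NULL, log_base = 10, eps = 1e-8,
                           norm_mode = "control_arith_mean") {
  norm <- match.arg(norm)
  validate_expression(expr)
  stopifnot(inherits(coll, "pathway_collection"))
  if (norm == "cohort_mean") {
    if (ncol(expr) < 2L)
      stop("cohort_mean norm needs >= 2 samples")
    ctrl <- expr
  } else {
    if (is.null(control_samples) ||
        !all(control_samples %in% colnames(expr)))
      stop("control_samples must name columns of expr")
    ctrl <- expr[, control_samples, drop = FALSE]
  }
  ids <- names(coll$pathways)
  pal <- matrix(NA_real_, nrow = ncol(expr), ncol = length(ids),
                dimnames = list(colnames(expr), ids))
  status <- stats::setNames(rep("scored", length(ids)), ids)
  for (s in colnames(expr)) {
    cnr <- compute_cnr(expr[, s, drop = FALSE], ctrl, eps = eps,
                       norm_mode = norm_mode)
    for (id in ids) {
      if (status[[id]] != "scored") next
      pal[s, id] <- tryCatch(
        as.numeric(compute_pal(cnr, coll$pathways[[id]],
                               log_base = log_base)),
        paslab_unmeasured = function(e) { status[[id]] <<- "unmeasured"; NA_real_ },
        paslab_unscorable = function(e) { status[[id]] <<- "unscorable"; NA_real_ })
    }
  }
  keep <- status == "scored"
  out <- pal[, keep, drop = FALSE]
  attr(out, "skipped") <- data.frame(pathway = ids[!keep],
                                     status = unname(status[!keep]),
                                     stringsAsFactors = FALSE)
  out
}

#' Count up- and down-regulated pathways
#'
#' @param pal numeric vector of PAL values (`NA`s, e.g. unscored pathways,
#'   are dropped).
#' @param threshold nonnegative regulation threshold; strict inequalities are
#'   used on both sides.
#' @return list with `n_up`, `n_down`, `n_total`, `frac_up`, `frac_down`
#'   (fractions over scorable pathways; 0 for empty input).
#' @export
count_regulated <- function(pal, threshold) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold >= 0)
  pal <- pal[!is.na(pal)]
  n <- length(pal)
  n_up <- sum(pal > threshold)
  n_down <- sum(pal < -threshold)
  list(n_up = n_up, n_down = n_down, n_total = n,
       frac_up = if (n > 0L) n_up / n else 0,
       frac_down = if (n > 0L) n_down / n else 0)
}
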