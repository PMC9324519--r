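## Cell-line panel analysis: gene-dependency scores (more negative = the
## line depends more on the gene; DEMETER2-style for RNAi, Chronos-style for
## CRISPR) grouped by tumor type, and drug-sensitivity AUC correlated with
## the dependency score of each annotated drug target. Per drug-target pair
## the Pearson correlation is computed separately in the RNAi and CRISPR
## channels over the shared cell lines, then the available channel
## correlations are averaged.

#' Construct a dependency panel
#'
#' @param scores numeric matrix, cell lines x genes (rownames = cell-line
#'   ids); `NA` for unscreened entries.
#' @param tumor_type named character vector cell line -> tumor type.
#' @param channel `"RNAi"` or `"CRISPR"`.
#' @return object of class `"dependency_panel"`.
#' @export
dependency_panel <- function(scores, tumor_type,
                             channel = c("RNAi", "CRISPR")) {
  channel <- match.arg(channel)
  if (!is.matrix(scores) || is.null(rownames(scores)) ||
      is.null(colnames(scores)))
    stop("scores must be a cell-line x gene matrix with dimnames")
  if (anyDuplicated(rownames(scores))) stop("duplicate cell-line ids")
  if (!all(rownames(scores) %in% names(tumor_type)))
    stop("every cell line needs a tumor_type entry")
  structure(list(scores = scores,
                 tumor_type = tumor_type[rownames(scores)],
                 channel = channel),
            class = "dependency_panel")
}

#' Read a long-format dependency CSV
#'
#' Columns: `cell_line`, `tumor_type`, `gene`, `score` (one channel per
#' file).
#'
#' @param path CSV path.
#' @param channel `"RNAi"` or `"CRISPR"`.
#' @return a [dependency_panel()].
#' @export
read_dependency_panel <- function(path, channel = c("RNAi", "CRISPR")) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_line", "tumor_type", "gene", "score")
  if (!all(need %in% colnames(d)))
    stop("dependency CSV needs columns: ", paste(need, collapse = ", "))
  lines <- unique(d$cell_line); genes <- unique(d$gene)
  m <- matrix(NA_real_, length(lines), length(genes),
              dimnames = list(lines, genes))
  m[cbind(d$cell_line, d$gene)] <- d$score
  tt <- stats::setNames(d$tumor_type, d$cell_line)[lines]
  dependency_panel(m, tt, channel = match.arg(channel))
}

#' Construct a drug panel
#'
#' @param auc numeric matrix, drugs x cell lines (`NA` for unmeasured);
#'   lower AUC = greater sensitivity.
#' @param targets named list drug -> character vector of target genes (every
#'   drug needs >= 1 target).
#' @return object of class `"drug_panel"`.
#' @export
drug_panel <- function(auc, targets) {
  if (!is.matrix(auc) || is.null(rownames(auc)) || is.null(colnames(auc)))
    stop("auc must be a drug x cell-line matrix with dimnames")
  if (!all(rownames(auc) %in% names(targets)))
    stop("every drug needs a target entry")
  if (any(lengths(targets[rownames(auc)]) == 0L))
    stop("every drug needs >= 1 target gene")
  if (any(is.infinite(auc))) stop("AUC values must be finite where present")
  structure(list(auc = auc, targets = targets[rownames(auc)]),
            class = "drug_panel")
}

#' Read drug AUCs and a drug-target map
#'
#' `drug_csv` columns: `drug`, `cell_line`, `auc`; `target_csv` columns:
#' `drug`, `target`.
#'
#' @param drug_csv,target_csv CSV paths.
#' @return a [drug_panel()].
#' @export
read_drug_panel <- function(drug_csv, target_csv) {
  d <- utils::read.csv(drug_csv, stringsAsFactors = FALSE)
  t <- utils::read.csv(target_csv, stringsAsFactors = FALSE)
  if (!all(c("drug", "cell_line", "auc") %in% colnames(d)))
    stop("drug CSV needs columns: drug, cell_line, auc")
  if (!all(c("drug", "target") %in% colnames(t)))
    stop("target CSV needs columns: drug, target")
  drugs <- unique(d$drug); lines <- unique(d$cell_line)
  m <- matrix(NA_real_, length(drugs), length(lines),
              dimnames = list(drugs, lines))
  m[cbind(d$drug, d$cell_line)] <- d$auc
  drug_panel(m, split(t$target, t$drug))
}

#' Summarize one gene's dependency by tumor type
#'
#' Median and quartiles of the gene's dependency score per tumor type,
#' restricted to types represented by strictly more than `min_lines` cell
#' lines with a non-missing score.
#'
#' @param dep a [dependency_panel()].
#' @param gene gene id present in the panel.
#' @param min_lines strict lower bound on cell lines per retained type.
#' @return data.frame (tumor_type, n, median, q1, q3), ordered by median;
#'   empty (with a warning) when no type passes the filter.
#' @export
group_dependency <- function(dep, gene, min_lines = 5) {
  stopifnot(inherits(dep, "dependency_panel"))
  if (!gene %in% colnames(dep$scores))
    stop("gene '", gene, "' absent from the ", dep$channel, " panel")
  sc <- dep$scores[, gene]
  keep <- !is.na(sc)
  d <- split(sc[keep], dep$tumor_type[keep])
  d <- d[vapply(d, length, integer(1L)) > min_lines]
  if (length(d) == 0L) {
    warning("no tumor type has more than ", min_lines,
            " cell lines with a '", gene, "' score")
    return(data.frame(tumor_type = character(0L), n = integer(0L),
                      median = numeric(0L), q1 = numeric(0L),
                      q3 = numeric(0L)))
  }
  out <- data.frame(
    tumor_type = names(d),
    n = vapply(d, length, integer(1L)),
    median = vapply(d, stats::median, numeric(1L)),
    q1 = vapply(d, stats::quantile, numeric(1L), probs = 0.25, names = FALSE),
    q3 = vapply(d, stats::quantile, numeric(1L), probs = 0.75, names = FALSE),
    stringsAsFactors = FALSE)
  out <- out[order(out$median), ]
  rownames(out) <- NULL
  out
}

#' Drug-target correlation averaged over screen channels
#'
#' For each drug and each of its annotated targets, Pearson-correlates the
#' drug's AUC with the target's dependency score over the cell lines shared
#' with each channel (RNAi, CRISPR) separately, then averages the available
#' channel correlations. Pairs with fewer than `min_shared` complete pairs in
#' a channel are missing for that channel; a pair present in one channel
#' yields that channel's correlation alone.
#'
#' @param drugs a [drug_panel()].
#' @param rnai,crispr [dependency_panel()] objects (either may be `NULL`).
#' @param min_shared minimum complete cell-line pairs per channel.
#' @return list with `mean_r` (drug x target matrix, `NA` where no channel
#'   was computable) and `detail` (data.frame drug, target, channel, r, n).
#' @export
drug_target_correlation <- function(drugs, rnai = NULL, crispr = NULL,
                                    min_shared = 3) {
  stopifnot(inherits(drugs, "drug_panel"))
  panels <- Filter(Negate(is.null), list(rnai, crispr))
  if (length(panels) == 0L) stop("need at least one dependency panel")
  targets <- sort(unique(unlist(drugs$targets)))
  drug_ids <- rownames(drugs$auc)
  mean_r <- matrix(NA_real_, length(drug_ids), length(targets),
                   dimnames = list(drug_ids, targets))
  detail <- list()
  for (dg in drug_ids) {
    auc <- drugs$auc[dg, ]
    for (tg in drugs$targets[[dg]]) {
      rs <- c()
      for (pan in panels) {
        if (!tg %in% colnames(pan$scores)) next
        shared <- intersect(names(auc), rownames(pan$scores))
        a <- auc[shared]; s <- pan$scores[shared, tg]
        ok <- stats::complete.cases(a, s)
        if (sum(ok) < min_shared) next
        r <- tryCatch(pearson_test(a[ok], s[ok])$r,
                      paslab_constant = function(e) NA_real_)
        if (is.na(r)) next
        rs <- c(rs, r)
        detail[[length(detail) + 1L]] <-
          data.frame(drug = dg, target = tg, channel = pan$channel,
                     r = r, n = sum(ok), stringsAsFactors = FALSE)
      }
      if (length(rs) > 0L) mean_r[dg, tg] <- mean(rs)
    }
  }
  detail <- if (length(detail) > 0L) do.call(rbind, detail) else
    data.frame(drug = character(0L), target = character(0L),
               channel = character(0L), r = numeric(0L), n = integer(0L))
  list(mean_r = mean_r, detail = detail)
}

#' Rank targets and cluster drugs from a mean-correlation table
#'
#' Targets are ordered by the mean of their available cells (descending: the
#' target whose dependency best tracks drug sensitivity first). Drugs are
#' clustered with Ward.D2 on Euclidean distance over the target columns;
#' missing cells are imputed with the column mean for the clustering distance
#' only (and the imputation count reported).
#'
#' @param mean_r drug x target matrix from [drug_target_correlation()].
#' @return list with `target_order` (character), `target_means` (named
#'   numeric, same order), `drug_hclust` ([stats::hclust] or `NULL` for < 2
#'   drugs), `n_imputed`.
#' @export
rank_targets <- function(mean_r) {
  if (!is.matrix(mean_r) || nrow(mean_r) == 0L || ncol(mean_r) == 0L)
    stop("mean_r table is empty")
  tmeans <- colMeans(mean_r, na.rm = TRUE)
  ord <- order(-tmeans, colnames(mean_r))  # ties broken by target name
  target_order <- colnames(mean_r)[ord]
  n_imputed <- sum(is.na(mean_r))
  filled <- mean_r
  if (n_imputed > 0L) {
    for (j in seq_len(ncol(filled))) {
      cm <- mean(filled[, j], na.rm = TRUE)
      if (is.nan(cm)) cm <- 0
      filled[is.na(filled[, j]), j] <- cm
    }
  }
  hc <- if (nrow(filled) >= 2L) {
    filled <- filled[order(rownames(filled)), , drop = FALSE]
    stats::hclust(stats::dist(filled, method = "euclidean"),
                  method = "ward.D2")
  } else NULL
  list(target_order = target_order, target_means = tmeans[ord],
       drug_hclust = hc, n_imputed = n_imputed)
}
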