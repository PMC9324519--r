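## Expression matrices are plain numeric matrices: genes in rows (unique
## rownames), samples in columns (unique colnames), nonnegative linear-scale
## values. Sample annotations travel in a separate data.frame
## (sample, cohort, group), limma-targets style.

.valid_groups <- c("case", "control", "none")

#' Validate a gene-by-sample expression matrix
#'
#' Checks the invariants every downstream function assumes: numeric matrix,
#' unique non-empty gene rownames and sample colnames, no negative values,
#' no missing values.
#'
#' @param m numeric matrix, genes x samples.
#' @param allow_na logical; tolerate `NA` entries (screens use
#'   pairwise-complete deletion; preprocessing does not).
#' @return `m`, invisibly, if valid; otherwise an error.
#' @export
validate_expression <- function(m, allow_na = FALSE) {
  if (!is.matrix(m) || !is.numeric(m))
    stop("expression data must be a numeric matrix (genes x samples)")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    stop("expression matrix must have unique gene rownames")
  if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
    stop("expression matrix must have unique sample colnames")
  if (!allow_na && anyNA(m))
    stop("expression matrix contains missing values")
  if (any(m < 0, na.rm = TRUE))
    stop("expression matrix contains negative values; linear-scale ",
         "intensities must be nonnegative")
  invisible(m)
}

#' Read a gene-by-sample expression table
#'
#' Reads a TSV (first column gene id, header of sample ids) or a GCT 1.2 file
#' (version line `#1.2`, dimensions line, `Name`/`Description` columns; the
#' Description column is ignored). Duplicate gene rows are collapsed by
#' arithmetic mean, with a message reporting how many groups were collapsed.
#'
#' @param path file path.
#' @param format `"tsv"` or `"gct"`.
#' @return numeric matrix, genes x samples, with an attribute
#'   `n_collapsed_genes` giving the number of duplicated gene ids collapsed.
#' @export
read_expression <- function(path, format = c("tsv", "gct")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "gct") {
    header <- readLines(path, n = 2L)
    if (length(header) < 2L || !startsWith(header[[1L]], "#1.2"))
      stop("malformed GCT header in ", path, ": expected version line '#1.2'")
    dims <- suppressWarnings(as.integer(strsplit(header[[2L]], "\t")[[1L]]))
    if (length(dims) < 2L || anyNA(dims[1:2]))
      stop("malformed GCT dimensions line in ", path)
    hdr <- strsplit(readLines(path, n = 3L)[[3L]], "\t", fixed = TRUE)[[1L]]
    if (!identical(hdr[1:2], c("Name", "Description")))
      stop("malformed GCT header in ", path,
           ": expected 'Name' and 'Description' columns")
    if (anyDuplicated(hdr[-(1:2)]))
      stop("duplicate sample id in ", path, ": ",
           paste(unique(hdr[-(1:2)][duplicated(hdr[-(1:2)])]),
                 collapse = ", "))
    raw <- utils::read.delim(path, skip = 2L, check.names = FALSE,
                             colClasses = "character")
    colnames(raw) <- hdr
    genes <- raw[[1L]]
    raw <- raw[, -(1:2), drop = FALSE]
    if (nrow(raw) != dims[[1L]] || ncol(raw) != dims[[2L]])
      stop("GCT dimensions line (", dims[[1L]], " x ", dims[[2L]],
           ") does not match data (", nrow(raw), " x ", ncol(raw), ")")
  } else {
    hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
    if (length(hdr) < 2L)
      stop("malformed header in ", path,
           ": expected a gene id column plus >= 1 sample column")
    if (anyDuplicated(hdr[-1L]))
      stop("duplicate sample id in ", path, ": ",
           paste(unique(hdr[-1L][duplicated(hdr[-1L])]), collapse = ", "))
    raw <- utils::read.delim(path, check.names = FALSE,
                             colClasses = "character")
    colnames(raw) <- hdr
    genes <- raw[[1L]]
    raw <- raw[, -1L, drop = FALSE]
  }
  vals <- vapply(raw, function(col) suppressWarnings(as.numeric(col)),
                 numeric(nrow(raw)))
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(NULL, colnames(raw)))
  bad <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("non-numeric cell in ", path, " at data row ", bad[1L, 1L],
         " (gene '", genes[bad[1L, 1L]], "', sample '",
         colnames(vals)[bad[1L, 2L]], "')")
  rownames(vals) <- genes
  out <- collapse_duplicate_genes(vals)
  validate_expression(out)
  out
}

#' Collapse duplicate gene rows by arithmetic mean
#'
#' @param m numeric matrix with gene rownames (duplicates allowed).
#' @return matrix with unique gene rownames, in first-appearance order;
#'   attribute `n_collapsed_genes` counts gene ids that had > 1 row.
#' @export
collapse_duplicate_genes <- function(m) {
  genes <- rownames(m)
  if (is.null(genes)) stop("matrix has no gene rownames")
  ndup <- sum(table(genes) > 1L)
  if (ndup > 0L) {
    keep_order <- unique(genes)
    counts <- as.vector(table(genes)[keep_order])
    m <- rowsum(m, group = genes, reorder = FALSE) / counts
    message(ndup, " duplicate gene id(s) collapsed by arithmetic mean")
  }
  attr(m, "n_collapsed_genes") <- ndup
  m
}

#' Write an expression matrix
#'
#' @param m numeric matrix, genes x samples.
#' @param path output file path.
#' @param format `"tsv"` or `"gct"`. In GCT output the Description column is
#'   written as the gene id.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path, format = c("tsv", "gct")) {
  format <- match.arg(format)
  validate_expression(m)
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (format == "gct") {
    writeLines(c("#1.2", paste(nrow(m), ncol(m), sep = "\t")), con)
    header <- paste(c("Name", "Description", colnames(m)), collapse = "\t")
    body <- paste(rownames(m), rownames(m),
                  apply(m, 1L, paste, collapse = "\t"), sep = "\t")
  } else {
    header <- paste(c("gene", colnames(m)), collapse = "\t")
    body <- paste(rownames(m), apply(m, 1L, paste, collapse = "\t"),
                  sep = "\t")
  }
  writeLines(c(header, body), con)
  invisible(path)
}

#' Read sample annotations
#'
#' A two- or three-column TSV: sample, cohort, and optionally group
#' (`case`, `control` or `none`; missing column means `none`).
#'
#' @param path file path.
#' @return data.frame with columns `sample`, `cohort`, `group`.
#' @export
read_sample_annotations <- function(path) {
  ann <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character")
  if (ncol(ann) < 2L)
    stop("annotation file needs at least columns (sample, cohort)")
  out <- data.frame(sample = ann[[1L]], cohort = ann[[2L]],
                    group = if (ncol(ann) >= 3L) ann[[3L]] else "none",
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$sample))
    stop("duplicate sample id in ", path)
  bad <- setdiff(unique(out$group), .valid_groups)
  if (length(bad) > 0L)
    stop("unknown group label(s) in ", path, ": ",
         paste(bad, collapse = ", "),
         " (expected ", paste(.valid_groups, collapse = "/"), ")")
  out
}

#' Aggregate replicate probes by geometric mean
#'
#' Collapses a probe-by-sample intensity matrix to one row per replicate
#' group (probes sharing an oligonucleotide sequence) by the geometric mean of
#' the member probe signals, then maps replicate groups to genes. Zero
#' intensities are floored to `eps` before log-averaging; flooring events are
#' counted and reported.
#'
#' @param values numeric matrix, probes x samples; rownames are probe ids.
#' @param probe_info data.frame with columns `probe_id`, `replicate_group`,
#'   `gene` (empty string or `NA` for unmapped probes).
#' @param eps positive flooring constant for zero intensities.
#' @param collapse_genes logical; if `TRUE`, additionally collapse rows
#'   mapping to the same gene by arithmetic mean (the default keeps one row
#'   per replicate group so that collapsing can be done after normalization).
#' @return numeric matrix with one row per replicate group (rownames are gene
#'   ids where mapped), restricted to groups with a gene assignment.
#'   Attributes: `n_floored` (count of floored intensities), `n_unmapped`
#'   (replicate groups dropped for lack of a gene).
#' @export
aggregate_probes <- function(values, probe_info, eps = 1e-8,
                             collapse_genes = FALSE) {
  if (!is.matrix(values) || nrow(values) == 0L)
    stop("empty probe set")
  stopifnot(eps > 0)
  need <- c("probe_id", "replicate_group", "gene")
  if (!all(need %in% colnames(probe_info)))
    stop("probe_info needs columns: ", paste(need, collapse = ", "))
  idx <- match(rownames(values), probe_info$probe_id)
  if (anyNA(idx))
    stop("probes missing from probe_info: ",
         paste(utils::head(rownames(values)[is.na(idx)], 3L), collapse = ", "))
  if (any(values < 0)) stop("negative probe intensities")
  n_floored <- sum(values < eps)
  if (n_floored > 0L) {
    values[values < eps] <- eps
    message(n_floored, " probe intensit(ies) floored to eps = ", eps)
  }
  grp <- probe_info$replicate_group[idx]
  n_per_grp <- as.vector(table(grp)[unique(grp)])
  gm <- exp(rowsum(log(values), group = grp, reorder = FALSE) / n_per_grp)

  gene_of <- probe_info$gene[idx][!duplicated(grp)]
  names(gene_of) <- unique(grp)
  gene_of <- gene_of[rownames(gm)]
  mapped <- !is.na(gene_of) & nzchar(gene_of)
  n_unmapped <- sum(!mapped)
  if (n_unmapped > 0L)
    message(n_unmapped, " replicate group(s) without gene mapping dropped")
  gm <- gm[mapped, , drop = FALSE]
  rownames(gm) <- gene_of[mapped]
  if (collapse_genes) gm <- collapse_duplicate_genes(gm)
  attr(gm, "n_floored") <- n_floored
  attr(gm, "n_unmapped") <- n_unmapped
  gm
}

#' Quantile normalization
#'
#' Forces every sample column onto the common reference distribution defined
#' as the row means of the column-sorted input. Within-column rank order is
#' preserved; tied values within a column receive the arithmetic mean of the
#' reference quantiles their sorted positions span.
#'
#' @param m numeric matrix, genes x samples, >= 2 samples, no missing values.
#' @return matrix of the same shape; every column holds the identical sorted
#'   value multiset when the input has no within-column ties.
#' @export
quantile_normalize <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stop("m must be a numeric matrix")
  if (ncol(m) < 2L)
    stop("quantile normalization needs >= 2 samples (nothing to ",
         "normalize across)")
  if (anyNA(m)) stop("quantile normalization requires complete data")
  ref <- rowMeans(apply(m, 2L, sort))
  out <- apply(m, 2L, function(x) {
    y <- numeric(length(x))
    y[order(x)] <- ref
    stats::ave(y, x, FUN = mean)  # ties -> mean of spanned reference values
  })
  dimnames(out) <- dimnames(m)
  out
}
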