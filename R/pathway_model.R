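## Pathways carry a signed activator/repressor role (ARR) per member gene:
##   -1   signal repressor
##   -0.5 more likely a repressor
##    0   ambivalent or neutral
##    0.5 more likely an activator
##    1   signal activator
## Collections are stored in a role-extended GMT dialect ("GMTX"):
##   <pathway id> <TAB> <class> <TAB> gene:role <TAB> gene:role ...
## with class in {signaling, metabolic}.

.arr_values <- c(-1, -0.5, 0, 0.5, 1)
.arr_tokens <- c("-1", "-0.5", "0", "0.5", "1")
.pathway_classes <- c("signaling", "metabolic")

#' Construct a pathway
#'
#' @param id pathway identifier.
#' @param members named numeric vector: gene -> ARR role in
#'   \{-1, -0.5, 0, 0.5, 1\}.
#' @param klass `"signaling"` or `"metabolic"`.
#' @param name display name (defaults to `id`).
#' @param n_original original member count before any restriction (kept for
#'   reporting when a pathway is restricted to measured genes).
#' @return object of class `"pathway"`.
#' @export
pathway <- function(id, members, klass = c("signaling", "metabolic"),
                    name = id, n_original = length(members)) {
  klass <- match.arg(klass)
  if (length(members) == 0L)
    stop("pathway '", id, "' has no members")
  if (is.null(names(members)) || any(!nzchar(names(members))))
    stop("pathway '", id, "' members must be a named numeric vector")
  if (anyDuplicated(names(members)))
    stop("duplicate gene in pathway '", id, "'")
  if (!all(members %in% .arr_values))
    stop("illegal ARR value in pathway '", id, "': roles must be one of ",
         paste(.arr_tokens, collapse = ", "))
  structure(list(id = id, name = name, klass = klass,
                 members = members, n_original = n_original),
            class = "pathway")
}

#' @export
print.pathway <- function(x, ...) {
  cat("<pathway> ", x$id, " (", x$klass, "), ", length(x$members),
      " member(s)\n", sep = "")
  invisible(x)
}

#' Construct a pathway collection
#'
#' @param pathways list of [pathway()] objects with unique ids.
#' @param source free-text provenance.
#' @return object of class `"pathway_collection"`; pathways are accessible by
#'   id via `coll$pathways[[id]]`.
#' @export
pathway_collection <- function(pathways, source = "in-memory") {
  ids <- vapply(pathways, `[[`, character(1L), "id")
  if (anyDuplicated(ids))
    stop("duplicate pathway id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(pathways) <- ids
  structure(list(pathways = pathways, source = source),
            class = "pathway_collection")
}

#' @export
print.pathway_collection <- function(x, ...) {
  kl <- vapply(x$pathways, `[[`, character(1L), "klass")
  cat("<pathway_collection> ", length(x$pathways), " pathway(s) (",
      sum(kl == "signaling"), " signaling, ", sum(kl == "metabolic"),
      " metabolic) from ", x$source, "\n", sep = "")
  invisible(x)
}

#' @export
length.pathway_collection <- function(x) length(x$pathways)

#' Read a pathway collection (GMTX or plain GMT)
#'
#' GMTX: one pathway per line,
#' `id<TAB>class<TAB>gene:role<TAB>gene:role...`, role tokens exactly
#' `-1`, `-0.5`, `0`, `0.5`, `1`. Plain GMT
#' (`name<TAB>description<TAB>gene...`) is accepted for unsigned sets: every
#' role defaults to +1 (with a warning) and the class to `"signaling"`.
#'
#' @param path file path.
#' @param format `"gmtx"` or `"gmt"`.
#' @return a [pathway_collection()].
#' @export
read_pathway_collection <- function(path, format = c("gmtx", "gmt")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty pathway file: ", path)
  pws <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("line ", i, " of ", path, ": expected id, class and >= 1 member")
    if (format == "gmt") {
      members <- f[-(1:2)]
      arr <- rep(1, length(members))
      names(arr) <- members
      klass <- "signaling"
    } else {
      klass <- f[[2L]]
      if (!klass %in% .pathway_classes)
        stop("line ", i, " of ", path, ": unknown pathway class '", klass, "'")
      toks <- strsplit(f[-(1:2)], ":", fixed = TRUE)
      bad <- which(lengths(toks) != 2L)
      if (length(bad) > 0L)
        stop("line ", i, " of ", path, ": malformed member token '",
             f[-(1:2)][bad[[1L]]], "' (expected gene:role)")
      genes <- vapply(toks, `[[`, character(1L), 1L)
      roles <- vapply(toks, `[[`, character(1L), 2L)
      ill <- which(!roles %in% .arr_tokens)
      if (length(ill) > 0L)
        stop("line ", i, " of ", path, ": illegal role value ':",
             roles[ill[[1L]]], "' for gene '", genes[ill[[1L]]],
             "' (legal roles: ", paste(.arr_tokens, collapse = ", "), ")")
      arr <- as.numeric(roles)
      names(arr) <- genes
      if (anyDuplicated(genes))
        stop("line ", i, " of ", path, ": duplicate gene '",
             genes[duplicated(genes)][[1L]], "'")
    }
    pws[[i]] <- pathway(f[[1L]], arr, klass)
  }
  if (format == "gmt")
    warning("plain GMT input: all roles defaulted to +1 (activator)")
  ids <- vapply(pws, `[[`, character(1L), "id")
  if (anyDuplicated(ids))
    stop("duplicate pathway id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  pathway_collection(pws, source = path)
}

#' Write a pathway collection in GMTX format
#'
#' @param coll a [pathway_collection()].
#' @param path output file path.
#' @return `path`, invisibly. Reading the file back reproduces the collection
#'   (up to the `source` field).
#' @export
write_pathway_collection <- function(coll, path) {
  stopifnot(inherits(coll, "pathway_collection"))
  fmt_role <- function(x) formatC(x, format = "fg")  # -1, -0.5, 0, 0.5, 1
  lines <- vapply(coll$pathways, function(p) {
    paste(c(p$id, p$klass,
            paste0(names(p$members), ":", fmt_role(p$members))),
          collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Restrict a pathway to measured genes
#'
#' Drops members absent from the measured gene set. A pathway with no
#' measured member signals a classed error (`paslab_unmeasured`), which batch
#' callers catch and report as skipped.
#'
#' @param p a [pathway()].
#' @param genes character vector of measured gene ids.
#' @return the restricted pathway; `n_original` keeps the pre-restriction
#'   member count.
#' @export
restrict_to_measured <- function(p, genes) {
  stopifnot(inherits(p, "pathway"))
  keep <- names(p$members) %in% genes
  if (!any(keep)) {
    cond <- structure(
      class = c("paslab_unmeasured", "error", "condition"),
      list(message = paste0("pathway '", p$id,
                            "' has no measured members (unmeasured)"),
           call = sys.call(-1L)))
    stop(cond)
  }
  pathway(p$id, p$members[keep], p$klass, name = p$name,
          n_original = p$n_original)
}
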