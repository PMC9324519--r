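## Seeded generators producing inputs with the statistical structure every
## pipeline stage assumes: multi-cohort log-normal expression with a
## "high-expressor" mixture component, case/control designs where pathway
## members shift coherently with their signed roles, signature genes sharing
## a latent factor with a driver gene at a calibrated correlation, and
## cell-line panels where one true target's dependency linearly predicts
## drug AUC. Expression is log-normal (positivity, as for microarray
## intensities); planted effects live on the log scale so PAL recovery
## targets are closed-form. Identical arguments + seed give identical
## output; the caller's RNG state is left untouched.

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate multi-cohort expression with a high-expressor mixture
#'
#' One gene of interest is drawn, per cohort, from a two-component
#' log2-normal mixture: a baseline component `N(mu, sigma^2)` and, with
#' probability `pi_high`, a component shifted upward by `shift` (log2 units).
#' All other genes are i.i.d. log2-normal at the cohort baseline. Values are
#' returned on the linear scale.
#'
#' @param cohorts data.frame with columns `cohort`, `n`, `mu`, `sigma`,
#'   `pi_high`, `shift` (one row per cohort; `mu`/`sigma`/`shift` in log2
#'   units).
#' @param n_genes total genes including the gene of interest.
#' @param gene name of the gene of interest.
#' @param seed integer seed.
#' @return list with `expr` (genes x samples, linear scale), `annotations`
#'   (data.frame sample, cohort, group = "none").
#' @export
gen_cohort_expression <- function(cohorts, n_genes = 20, gene = "KIT",
                                  seed = 1) {
  need <- c("cohort", "n", "mu", "sigma", "pi_high", "shift")
  if (!all(need %in% colnames(cohorts)))
    stop("cohorts needs columns: ", paste(need, collapse = ", "))
  stopifnot(all(cohorts$sigma > 0), all(cohorts$pi_high >= 0),
            all(cohorts$pi_high <= 1), all(cohorts$n >= 1))
  with_seed(seed, {
    blocks <- lapply(seq_len(nrow(cohorts)), function(i) {
      co <- cohorts[i, ]
      hi <- stats::rbinom(co$n, 1L, co$pi_high)
      goi <- co$mu + co$sigma * stats::rnorm(co$n) + co$shift * hi
      bg <- matrix(co$mu + co$sigma * stats::rnorm((n_genes - 1L) * co$n),
                   nrow = n_genes - 1L)
      rbind(goi, bg)
    })
    m <- 2^do.call(cbind, blocks)
    rownames(m) <- c(gene, sprintf("BG%03d", seq_len(n_genes - 1L)))
    colnames(m) <- sprintf("S%04d", seq_len(ncol(m)))
    ann <- data.frame(sample = colnames(m),
                      cohort = rep(cohorts$cohort, cohorts$n),
                      group = "none", stringsAsFactors = FALSE)
    list(expr = m, annotations = ann)
  })
}

#' Generate a disjoint role-annotated pathway collection
#'
#' Synthetic pathways with non-overlapping member genes and mixed
#' activator/repressor roles, for demos and tests.
#'
#' @param n_signaling,n_metabolic pathway counts per class.
#' @param n_members members per pathway.
#' @param seed integer seed.
#' @return a [pathway_collection()].
#' @export
gen_pathway_collection <- function(n_signaling = 3, n_metabolic = 3,
                                   n_members = 6, seed = 1) {
  stopifnot(n_signaling + n_metabolic >= 1, n_members >= 1)
  with_seed(seed, {
    total <- n_signaling + n_metabolic
    klass <- rep(c("signaling", "metabolic"), c(n_signaling, n_metabolic))
    genes <- sprintf("G%04d", seq_len(total * n_members))
    pws <- lapply(seq_len(total), function(i) {
      g <- genes[((i - 1L) * n_members + 1L):(i * n_members)]
      roles <- sample(c(-1, -0.5, 0.5, 1), n_members, replace = TRUE)
      roles[1L] <- 1  # guarantee a non-neutral member
      pathway(sprintf("PW%02d", i), stats::setNames(roles, g), klass[[i]])
    })
    pathway_collection(pws, source = "synthetic")
  })
}

#' Generate a case/control dataset with one planted activated pathway
#'
#' Control samples are log10-normal around per-gene baselines; in case
#' samples the activated pathway's activator members (`ARR > 0`) are shifted
#' by `+delta` and its repressor members (`ARR < 0`) by `-delta` on the log10
#' scale, plus per-observation Gaussian log-noise `sigma`. All other genes
#' are unshifted, so with `sigma = 0` the planted pathway's PAL equals
#' `delta` exactly (log base 10) and disjoint pathways score 0.
#'
#' @param coll a [pathway_collection()].
#' @param activated id of the pathway to activate.
#' @param delta planted shift (log10 units).
#' @param n_case,n_ctrl sample counts.
#' @param sigma per-observation log10 noise SD (>= 0).
#' @param seed integer seed.
#' @param n_extra_genes unannotated background genes.
#' @return list with `expr` (linear scale), `design` (sample, group).
#' @export
gen_pathway_dataset <- function(coll, activated, delta = 1, n_case = 3,
                                n_ctrl = 3, sigma = 0, seed = 1,
                                n_extra_genes = 10) {
  stopifnot(inherits(coll, "pathway_collection"), sigma >= 0,
            n_case >= 1, n_ctrl >= 1)
  if (!activated %in% names(coll$pathways))
    stop("pathway '", activated, "' not in the collection")
  with_seed(seed, {
    genes <- unique(c(unlist(lapply(coll$pathways,
                                    function(p) names(p$members))),
                      if (n_extra_genes > 0L)
                        sprintf("EX%03d", seq_len(n_extra_genes))))
    mu <- stats::setNames(2 + 0.3 * stats::rnorm(length(genes)), genes)
    shift <- stats::setNames(numeric(length(genes)), genes)
    arr <- coll$pathways[[activated]]$members
    shift[names(arr)[arr > 0]] <- delta
    shift[names(arr)[arr < 0]] <- -delta
    n <- n_case + n_ctrl
    noise <- matrix(if (sigma > 0) sigma * stats::rnorm(length(genes) * n)
                    else 0, nrow = length(genes), ncol = n)
    lg <- mu + noise
    lg[, seq_len(n_case)] <- lg[, seq_len(n_case), drop = FALSE] + shift
    m <- 10^lg
    dimnames(m) <- list(genes,
                        c(sprintf("case%02d", seq_len(n_case)),
                          sprintf("ctrl%02d", seq_len(n_ctrl))))
    design <- data.frame(sample = colnames(m),
                         group = rep(c("case", "control"),
                                     c(n_case, n_ctrl)),
                         stringsAsFactors = FALSE)
    list(expr = m, design = design)
  })
}

#' Generate driver-correlated signature expression
#'
#' A latent standard-normal factor drives the driver gene's log2 expression;
#' each signature's member genes load on the same factor with a per-gene
#' loading calibrated so that the signature's mean-square score correlates
#' with the driver at approximately the requested population `rho` (the
#' loading solves `w^2 = rho^2 / (K (1 - rho^2) + rho^2)` for a K-gene
#' signature, so that averaging over members lands the score's latent
#' correlation at `rho`). Non-signature genes are independent. Log-scale SDs
#' are kept moderate so the lognormal transform perturbs the correlation
#' only slightly.
#'
#' @param sigs named list: signature -> character vector of gene names.
#' @param rho named numeric: signature -> target correlation, `|rho| < 1`.
#' @param n_samples sample count.
#' @param seed integer seed.
#' @param driver driver gene name.
#' @param n_noise_genes independent background genes.
#' @param mu,sd log2 baseline mean and SD.
#' @return numeric matrix (linear scale), genes x samples: driver, all
#'   signature genes, background genes.
#' @export
gen_signature_dataset <- function(sigs, rho, n_samples = 100, seed = 1,
                                  driver = "KIT", n_noise_genes = 20,
                                  mu = 6, sd = 0.5) {
  stopifnot(is.list(sigs), length(sigs) >= 1, n_samples >= 3)
  if (!all(names(sigs) %in% names(rho)))
    stop("rho must name every signature")
  if (any(abs(rho) >= 1)) stop("|rho| must be < 1")
  with_seed(seed, {
    z <- stats::rnorm(n_samples)
    rows <- list()
    rows[[driver]] <- mu + sd * z
    for (sg in names(sigs)) {
      K <- length(sigs[[sg]])
      r <- rho[[sg]]
      w <- sign(r) * sqrt(r^2 / (K * (1 - r^2) + r^2))
      for (g in sigs[[sg]]) {
        eps <- stats::rnorm(n_samples)
        rows[[g]] <- mu + sd * (w * z + sqrt(1 - w^2) * eps)
      }
    }
    for (i in seq_len(n_noise_genes))
      rows[[sprintf("NZ%03d", i)]] <- mu + sd * stats::rnorm(n_samples)
    m <- 2^do.call(rbind, rows)
    colnames(m) <- sprintf("S%04d", seq_len(n_samples))
    m
  })
}

#' Generate linked drug-sensitivity and dependency panels
#'
#' Dependency scores are i.i.d. standard normal per channel, except each
#' drug's true target, whose score is shared between the RNAi and CRISPR
#' channels (the same underlying dependency measured twice). Each drug's AUC
#' is `slope * dependency(true target) + noise`, with the noise SD set to
#' `noise_ratio` times the signal SD.
#'
#' @param n_lines cell-line count.
#' @param genes character vector of panel genes (must contain all true
#'   targets).
#' @param true_target named character: drug -> its true target gene.
#' @param slope linear coefficient linking dependency to AUC (negative slope
#'   gives negative correlations).
#' @param noise_ratio noise SD as a fraction of signal SD (>= 0).
#' @param seed integer seed.
#' @param tumor_types labels recycled over cell lines.
#' @return list with `drugs` ([drug_panel()]; targets = all panel genes per
#'   drug, so ranking must find the true one), `rnai`, `crispr`
#'   ([dependency_panel()]).
#' @export
gen_pharm_panel <- function(n_lines = 60, genes = sprintf("T%02d", 1:8),
                            true_target = c(drugA = "T01"), slope = 1,
                            noise_ratio = 0.5, seed = 1,
                            tumor_types = c("NB", "AML", "lung", "breast")) {
  stopifnot(n_lines >= 3, noise_ratio >= 0, length(true_target) >= 1)
  if (!all(true_target %in% genes))
    stop("every true target must be among the panel genes")
  with_seed(seed, {
    lines <- sprintf("CL%03d", seq_len(n_lines))
    shared <- unique(unname(true_target))
    latent <- matrix(stats::rnorm(n_lines * length(shared)),
                     nrow = n_lines, dimnames = list(lines, shared))
    chan <- function() {
      m <- matrix(stats::rnorm(n_lines * length(genes)), nrow = n_lines,
                  dimnames = list(lines, genes))
      m[, shared] <- latent
      m
    }
    rnai_m <- chan(); crispr_m <- chan()
    tt <- stats::setNames(rep_len(tumor_types, n_lines), lines)
    auc <- t(vapply(names(true_target), function(dg) {
      sig <- slope * latent[, true_target[[dg]]]
      sig + stats::rnorm(n_lines, sd = noise_ratio * abs(slope))
    }, numeric(n_lines)))
    rownames(auc) <- names(true_target)
    list(drugs = drug_panel(auc, lapply(true_target, function(x) genes)),
         rnai = dependency_panel(rnai_m, tt, "RNAi"),
         crispr = dependency_panel(crispr_m, tt, "CRISPR"))
  })
}
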