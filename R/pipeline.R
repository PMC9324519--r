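## End-to-end synthetic workflow: simulate -> PAS -> screens -> pharm, with
## every parameter echoed into a manifest alongside md5 checksums of every
## file written. Reruns with an identical config (and seed) are
## byte-identical.

#' Default pipeline configuration
#'
#' @return named list of pipeline parameters; see [run_pipeline()].
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    alpha = 0.05,
    r_min = 0.2,
    log_base = 10,
    eps = 1e-8,
    regulation_threshold = 0.2,
    pathways = NULL,            # GMTX path; NULL -> synthetic collection
    pathway_effect = list(activated = "PW01", delta = 1,
                          n_case = 3, n_ctrl = 3, sigma = 0.05),
    signature_rho = c(SIG_A = 0.8, SIG_B = 0.3, SIG_NULL = 0),
    signature_size = 5L,
    screen_n_samples = 100L,
    pharm = list(n_lines = 60L, noise_ratio = 0.5, slope = 1,
                 true_target = c(drugA = "T01", drugB = "T03")),
    cohorts = data.frame(
      cohort = c("NB", "AML", "CLL", "lung"),
      n = c(120L, 80L, 80L, 120L),
      mu = c(6, 8, 4, 6),
      sigma = c(0.8, 0.8, 0.8, 0.8),
      pi_high = c(0.25, 0.9, 0, 0.02),
      shift = c(3, 0, 0, 3),
      stringsAsFactors = FALSE)
  )
}

read_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    user <- yaml::read_yaml(config)
  } else if (is.list(config)) {
    user <- config
  } else stop("config must be a YAML path or a list")
  cfg <- default_pipeline_config()
  for (k in names(user)) {
    cfg[[k]] <- if (is.list(cfg[[k]]) && is.list(user[[k]]) &&
                    !is.data.frame(cfg[[k]]))
      utils::modifyList(cfg[[k]], user[[k]]) else user[[k]]
  }
  if (is.list(cfg$cohorts) && !is.data.frame(cfg$cohorts))
    cfg$cohorts <- do.call(rbind,
      lapply(cfg$cohorts, function(r) as.data.frame(r,
                                                    stringsAsFactors = FALSE)))
  if (is.list(cfg$signature_rho)) cfg$signature_rho <- unlist(cfg$signature_rho)
  if (is.list(cfg$pharm$true_target))
    cfg$pharm$true_target <- unlist(cfg$pharm$true_target)
  cfg
}

validate_pipeline_config <- function(cfg) {
  stopifnot(cfg$alpha > 0, cfg$alpha < 1, cfg$r_min >= 0, cfg$log_base > 1,
            cfg$eps > 0, cfg$regulation_threshold >= 0)
  if (!is.null(cfg$pathways) && !file.exists(cfg$pathways))
    stop("pathway file not found: ", cfg$pathways)
  invisible(cfg)
}

.write_csv <- function(d, path) {
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  path
}

#' Run the full synthetic analysis pipeline
#'
#' Executes, in order: synthetic pathway-activation dataset generation and
#' case-vs-control PAL scoring with regulated-pathway counts; per-sample PAS
#' and its association with a driver gene; cohort distribution building,
#' Ward.D2 clustering and the high-expressor-fraction statistic; the
#' signature correlation screen under two-stage FDR; and the drug-target
#' dependency correlation analysis with target ranking. Every output CSV and
#' its md5 checksum, plus the full parameter set, is recorded in
#' `manifest.json`. Identical config + seed reproduce byte-identical outputs.
#'
#' @param config a config list or YAML file path (missing fields take
#'   [default_pipeline_config()] values).
#' @param out_dir output directory (created if needed).
#' @return invisibly, the manifest as a list (`params`, `files`).
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = "paslab_run") {
  cfg <- validate_pipeline_config(read_pipeline_config(config))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(out_dir, f)
  files <- character(0L)
  emit <- function(d, f) { files <<- c(files, .write_csv(d, out(f))); NULL }

  ## -- pathway collection ------------------------------------------------
  coll <- if (is.null(cfg$pathways)) {
    gen_pathway_collection(n_signaling = 3, n_metabolic = 3,
                           n_members = 6, seed = cfg$seed)
  } else read_pathway_collection(cfg$pathways)
  write_pathway_collection(coll, out("pathways.gmtx"))
  files <- c(files, out("pathways.gmtx"))
  pe <- cfg$pathway_effect
  if (!pe$activated %in% names(coll$pathways))
    stop("stage pas: activated pathway '", pe$activated,
         "' not in collection")

  ## -- stage: simulate + PAS --------------------------------------------
  ds <- gen_pathway_dataset(coll, activated = pe$activated,
                            delta = pe$delta, n_case = pe$n_case,
                            n_ctrl = pe$n_ctrl, sigma = pe$sigma,
                            seed = cfg$seed)
  write_expression(ds$expr, out("expression.tsv"))
  files <- c(files, out("expression.tsv"))
  emit(ds$design, "design.csv")
  pal <- pas_table(ds$expr, ds$design, coll, log_base = cfg$log_base,
                   eps = cfg$eps)
  emit(pal, "pal.csv")
  reg <- count_regulated(pal$pal, cfg$regulation_threshold)
  emit(data.frame(threshold = cfg$regulation_threshold,
                  n_up = reg$n_up, n_down = reg$n_down,
                  n_total = reg$n_total, frac_up = reg$frac_up,
                  frac_down = reg$frac_down), "regulated_counts.csv")

  ## -- stage: per-sample PAS + driver association ------------------------
  psp <- per_sample_pas(ds$expr, coll, norm = "cohort_mean",
                        log_base = cfg$log_base, eps = cfg$eps)
  emit(data.frame(sample = rownames(psp), psp, check.names = FALSE),
       "per_sample_pas.csv")
  driver_gene <- names(coll$pathways[[pe$activated]]$members)[[1L]]
  assoc <- pas_association(psp, ds$expr[driver_gene, ], alpha = cfg$alpha)
  emit(assoc$records, "pas_association.csv")

  ## -- stage: cohort distributions --------------------------------------
  coh <- gen_cohort_expression(cfg$cohorts, seed = cfg$seed + 1L)
  goi <- rownames(coh$expr)[[1L]]
  lvals <- log2_intensity(coh$expr[goi, ])
  edges <- default_bin_edges(lvals, n_bins = 32)
  by_cohort <- split(lvals, coh$annotations$cohort[
    match(names(lvals), coh$annotations$sample)])
  dists <- lapply(names(by_cohort), function(co)
    build_distribution(by_cohort[[co]], edges, cohort = co))
  emit(do.call(rbind, lapply(dists, function(d)
    data.frame(cohort = d$cohort, bin = seq_along(d$freqs),
               freq = d$freqs))), "distributions.csv")
  hc <- cluster_distributions(dists)
  emit(data.frame(step = seq_len(nrow(hc$merge)), left = hc$merge[, 1L],
                  right = hc$merge[, 2L], height = hc$height),
       "distribution_merges.csv")
  ref <- by_cohort[["AML"]]
  if (is.null(ref)) ref <- by_cohort[[1L]]
  hf <- do.call(rbind, lapply(names(by_cohort), function(co) {
    h <- high_fraction(by_cohort[[co]], ref)
    data.frame(cohort = co, fraction = h$fraction,
               threshold = h$threshold, is_high = h$is_high_cohort)
  }))
  emit(hf, "high_fraction.csv")

  ## -- stage: signature screen -------------------------------------------
  sig_genes <- lapply(seq_along(cfg$signature_rho), function(i)
    sprintf("SG%02d_%02d", i, seq_len(cfg$signature_size)))
  names(sig_genes) <- names(cfg$signature_rho)
  sigm <- gen_signature_dataset(sig_genes, cfg$signature_rho,
                                n_samples = cfg$screen_n_samples,
                                seed = cfg$seed + 2L)
  scores <- do.call(rbind, lapply(names(sig_genes), function(sg)
    signature_score(sigm, sig_genes[[sg]])))
  rownames(scores) <- names(sig_genes)
  scr <- correlation_screen(sigm["KIT", ], scores, alpha = cfg$alpha,
                            r_min = cfg$r_min)
  emit(scr$records, "screen_records.csv")
  emit(scr$counts, "screen_counts.csv")

  ## -- stage: pharm -------------------------------------------------------
  ph <- cfg$pharm
  panel <- gen_pharm_panel(n_lines = ph$n_lines,
                           true_target = ph$true_target,
                           slope = ph$slope, noise_ratio = ph$noise_ratio,
                           seed = cfg$seed + 3L)
  dtc <- drug_target_correlation(panel$drugs, panel$rnai, panel$crispr)
  emit(data.frame(drug = rownames(dtc$mean_r), dtc$mean_r,
                  check.names = FALSE), "drug_target_mean_r.csv")
  rk <- rank_targets(dtc$mean_r)
  emit(data.frame(rank = seq_along(rk$target_order),
                  target = rk$target_order,
                  mean_r = unname(rk$target_means)), "target_ranking.csv")
  if (!is.null(rk$drug_hclust))
    emit(data.frame(step = seq_len(nrow(rk$drug_hclust$merge)),
                    left = rk$drug_hclust$merge[, 1L],
                    right = rk$drug_hclust$merge[, 2L],
                    height = rk$drug_hclust$height), "drug_merges.csv")

  ## -- manifest -----------------------------------------------------------
  manifest <- list(
    params = cfg[!vapply(cfg, is.null, logical(1L))],
    files = data.frame(file = basename(files),
                       md5 = unname(tools::md5sum(files)),
                       stringsAsFactors = FALSE))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "rows")
  invisible(manifest)
}
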