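test_that("case-to-normal ratios follow the mean-over-means definition", {
  case <- matrix(c(10, 4), 2, dimnames = list(c("g1", "g2"), "c1"))
  case <- cbind(case, c2 = c(10, 6))
  ctrl <- matrix(c(5, 1, 5, 2, 5, 3), 2,
                 dimnames = list(c("g1", "g2"), c("n1", "n2", "n3")))
  cnr <- compute_cnr(case, ctrl)
  expect_equal(cnr$cnr[["g1"]], 2.0)          # 10 / mean(5,5,5)
  expect_equal(cnr$cnr[["g2"]], 2.5)          # mean(4,6) / mean(1,2,3)
  expect_equal(cnr$norm_mode, "control_arith_mean")
  expect_length(cnr$floored_genes, 0L)
})

test_that("zero controls are floored and recorded", {
  case <- matrix(5, 1, 1, dimnames = list("g1", "c1"))
  ctrl <- matrix(0, 1, 2, dimnames = list("g1", c("n1", "n2")))
  cnr <- compute_cnr(case, ctrl, eps = 1e-8)
  expect_equal(cnr$cnr[["g1"]], 5 / 1e-8)
  expect_equal(cnr$floored_genes, "g1")
  expect_error(compute_cnr(case, ctrl[, 0, drop = FALSE]), ">= 1 sample")
  expect_error(compute_cnr(case,
                           matrix(1, 1, 1, dimnames = list("zz", "n1"))),
               "no genes")
})

test_that("PAL evaluates the role-weighted log-ratio formula", {
  mk_cnr <- function(v) structure(list(cnr = v, norm_mode = "control_arith_mean",
                                       floored_genes = character(0)),
                                  class = "cnr")
  # single activator, CNR 10, base 10 -> log10(10) = 1
  expect_equal(as.numeric(compute_pal(mk_cnr(c(A = 10)),
                                      pathway("P", c(A = 1)))), 1.0)
  # all CNR = 1 -> 0 for any pathway
  expect_equal(as.numeric(compute_pal(mk_cnr(c(A = 1, B = 1)),
                                      pathway("P", c(A = 1, B = -0.5)))), 0)
  # {A:+1, B:-1, C:0}, CNR {100, 0.01, 5} -> (2 + 2 + 0) / 2 = 2
  pal <- compute_pal(mk_cnr(c(A = 100, B = 0.01, C = 5)),
                     pathway("P", c(A = 1, B = -1, C = 0)))
  expect_equal(as.numeric(pal), 2.0)
  expect_equal(attr(pal, "n_members_used"), 3L)
  # all measured members neutral -> unscorable
  expect_error(compute_pal(mk_cnr(c(C = 5)),
                           pathway("P", c(A = 1, C = 0))),
               class = "paslab_unscorable")
})

test_that("batch PAL matches the naive per-gene-loop oracle", {
  set.seed(101)
  for (i in 1:25) {
    inst <- random_pal_instance()
    cnr <- compute_cnr(inst$case, inst$control)
    expected <- pal_naive(cnr$cnr, inst$pathway$members)
    got <- tryCatch(as.numeric(compute_pal(cnr, inst$pathway)),
                    paslab_unscorable = function(e) NA_real_)
    expect_equal(got, expected, tolerance = 1e-10)
  }
})

test_that("PAL is antisymmetric under case/control swap and scale
           invariant", {
  set.seed(7)
  inst <- random_pal_instance()
  fwd <- as.numeric(compute_pal(compute_cnr(inst$case, inst$control),
                                inst$pathway))
  rev <- as.numeric(compute_pal(compute_cnr(inst$control, inst$case),
                                inst$pathway))
  expect_equal(fwd, -rev, tolerance = 1e-12)
  scaled <- as.numeric(compute_pal(compute_cnr(inst$case * 7.3,
                                               inst$control * 7.3),
                                   inst$pathway))
  expect_equal(scaled, fwd, tolerance = 1e-12)
})

test_that("neutral members never change PAL", {
  set.seed(8)
  inst <- random_pal_instance()
  cnr <- compute_cnr(inst$case, inst$control)
  arr <- inst$pathway$members
  extra <- setdiff(rownames(inst$expr), names(arr))[1:3]
  arr2 <- c(arr, stats::setNames(rep(0, 3), extra))
  p1 <- tryCatch(as.numeric(compute_pal(cnr, inst$pathway)),
                 paslab_unscorable = function(e) NA_real_)
  p2 <- tryCatch(as.numeric(compute_pal(cnr, pathway("P2", arr2))),
                 paslab_unscorable = function(e) NA_real_)
  expect_equal(p2, p1)
})

test_that("pas_table scores scorable pathways and reports the rest", {
  coll <- pathway_collection(list(
    pathway("OK1", c(A = 1, B = -1)),
    pathway("OK2", c(C = 0.5)),
    pathway("GONE", c(Z1 = 1, Z2 = 1))), source = "test")
  genes <- c("A", "B", "C")
  expr <- matrix(c(10, 1, 5, 10, 1, 5, 1, 1, 5, 1, 1, 5), nrow = 3,
                 dimnames = list(genes, c("c1", "c2", "n1", "n2")))
  design <- data.frame(sample = c("c1", "c2", "n1", "n2"),
                       group = c("case", "case", "control", "control"))
  tab <- pas_table(expr, design, coll)
  expect_equal(tab$status, c("scored", "scored", "unmeasured"))
  expect_equal(sum(!is.na(tab$pal)), 2L)
  expect_error(pas_table(expr, design[design$group == "case", ], coll),
               "case and >= 1 control")
})

test_that("identical case and control groups give PAL 0 everywhere", {
  coll <- tiny_collection()
  genes <- unique(unlist(lapply(coll$pathways, function(p) names(p$members))))
  set.seed(3)
  half <- matrix(10^rnorm(length(genes) * 2, 1, 0.3), length(genes),
                 dimnames = list(genes, c("s1", "s2")))
  expr <- cbind(half, half)
  colnames(expr) <- c("c1", "c2", "n1", "n2")
  design <- data.frame(sample = colnames(expr),
                       group = c("case", "case", "control", "control"))
  tab <- pas_table(expr, design, coll)
  expect_true(all(abs(tab$pal[tab$status == "scored"]) < 1e-12))
})

test_that("a planted ten-fold activation recovers PAL = 1 exactly", {
  coll <- gen_pathway_collection(n_signaling = 2, n_metabolic = 2,
                                 n_members = 5, seed = 21)
  ds <- gen_pathway_dataset(coll, "PW02", delta = 1, sigma = 0, seed = 22)
  tab <- pas_table(ds$expr, ds$design, coll)
  expect_equal(tab$pal[tab$pathway == "PW02"], 1.0)
  expect_true(all(tab$pal[tab$pathway != "PW02"] == 0))
})

test_that("per-sample PAS behaves under the cohort-mean norm", {
  coll <- tiny_collection()
  genes <- unique(unlist(lapply(coll$pathways, function(p) names(p$members))))
  set.seed(9)
  base <- 10^rnorm(length(genes), 1, 0.2)
  # two identical samples: both rows identical and all PAL = 0
  expr <- matrix(rep(base, 2), ncol = 2,
                 dimnames = list(genes, c("s1", "s2")))
  psp <- per_sample_pas(expr, coll)
  expect_equal(psp["s1", ], psp["s2", ])
  expect_true(all(abs(psp) < 1e-12))
})

test_that("a planted per-sample gradient in activators yields monotone PAS", {
  p <- pathway("GRAD", c(A = 1, B = 1), "signaling")
  coll <- pathway_collection(list(p), source = "test")
  grad <- 10^seq(0, 1, length.out = 5)
  expr <- rbind(A = grad, B = grad)
  colnames(expr) <- sprintf("s%d", 1:5)
  psp <- per_sample_pas(expr, coll)
  expect_false(is.unsorted(psp[, "GRAD"], strictly = TRUE))
})

test_that("count_regulated uses strict thresholds on both sides", {
  r <- count_regulated(c(1.2, -0.5, 0.0), threshold = 0.3)
  expect_equal(r[c("n_up", "n_down", "n_total")],
               list(n_up = 1L, n_down = 1L, n_total = 3L))
  r0 <- count_regulated(0.0, threshold = 0)
  expect_equal(r0$n_up + r0$n_down, 0L)
  rneg <- count_regulated(c(-1, -2, -0.1), threshold = 0)
  expect_equal(rneg$frac_down, 1.0)
  expect_equal(count_regulated(numeric(0), 1)$frac_up, 0)
})

test_that("planted-shift estimator noise shrinks with pathway size", {
  # per-gene log10 noise sigma; PAL averages member contributions, so its
  # SD over replicates should shrink roughly as 1/sqrt(n_members)
  sd_for <- function(n_members, n_rep = 60, sigma = 0.4) {
    p <- pathway("P", stats::setNames(rep(1, n_members),
                                      sprintf("m%02d", seq_len(n_members))))
    coll <- pathway_collection(list(p), source = "sim")
    vapply(seq_len(n_rep), function(i) {
      ds <- gen_pathway_dataset(coll, "P", delta = 1, n_case = 1,
                                n_ctrl = 1, sigma = sigma, seed = 5000 + i,
                                n_extra_genes = 0)
      pas_table(ds$expr, ds$design, coll)$pal[[1L]]
    }, numeric(1L)) |> stats::sd()
  }
  s4 <- sd_for(4); s16 <- sd_for(16)
  expect_lt(s16, s4)                      # shrinks with size...
  expect_equal(s4 / s16, 2, tolerance = 0.5)  # ...roughly as 1/sqrt(n)
})
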