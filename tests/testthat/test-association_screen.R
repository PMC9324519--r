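test_that("signature scores are mean squared expression", {
  expr <- matrix(c(1, 2, 0, 0, 3, 4), nrow = 3, byrow = TRUE,
                 dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  sc <- signature_score(expr, c("A", "B"))
  expect_equal(unname(sc["s1"]), (1 + 0) / 2)
  expect_equal(unname(sc["s2"]), (4 + 0) / 2)
  expect_equal(unname(signature_score(expr, c("A", "B"))["s1"]), 0.5)
  # {1, 2} in one sample -> (1 + 4) / 2
  expect_equal(unname(signature_score(expr[, "s2", drop = FALSE],
                                      c("A", "C"))[1]), (4 + 16) / 2)
  # single-gene signature -> x^2; all-zero expression -> 0
  expect_equal(as.numeric(signature_score(expr, "C")), c(9, 16))
  expect_equal(as.numeric(signature_score(expr * 0, c("A", "B"))), c(0, 0))
  # rms option is the square root of the mean-square score
  expect_equal(signature_score(expr, c("A", "C"), method = "rms"),
               sqrt(signature_score(expr, c("A", "C"))),
               ignore_attr = TRUE)
  expect_error(signature_score(expr, c("X", "Y")), "no signature gene")
  expect_equal(attr(signature_score(expr, c("A", "X")), "n_missing"), 1L)
})

test_that("signature score is monotone in member absolute expression", {
  expr <- matrix(c(1, 2, 3, 4), 2, dimnames = list(c("A", "B"),
                                                   c("s1", "s2")))
  bumped <- expr; bumped["A", "s1"] <- 10
  expect_gt(signature_score(bumped, c("A", "B"))[["s1"]],
            signature_score(expr, c("A", "B"))[["s1"]])
})

test_that("Pearson test matches hand-computed values and flags constants", {
  x <- 1:10
  perfect <- pearson_test(x, 2 * x + 1)
  expect_equal(perfect$r, 1.0)
  tri <- pearson_test(c(1, 2, 3), c(1, 3, 2))
  expect_equal(tri$r, 0.5)
  expect_equal(tri$n, 3L)
  expect_error(pearson_test(rep(1, 5), rnorm(5)), class = "paslab_constant")
  expect_error(pearson_test(1:2, 1:2), ">= 3")
  # pairwise-complete deletion
  pc <- pearson_test(c(1, 2, 3, NA, 5), c(2, 4, 6, 8, NA))
  expect_equal(pc$n, 3L)
  expect_equal(pc$r, 1.0)
})

test_that("two-stage FDR handles the trivial extremes", {
  all1 <- fdr_twostage(rep(1, 6))
  expect_false(any(all1$reject))
  all0 <- fdr_twostage(rep(0, 6))
  expect_true(all(all0$reject))
  expect_equal(all0$m0, 0L)
  empty <- fdr_twostage(numeric(0))
  expect_length(empty$q, 0L)
  expect_error(fdr_twostage(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("two-stage FDR matches the brute-force staged step-up on an
           exhaustive battery", {
  grid <- c(0.001, 0.02, 0.04, 0.8)
  # every monotone 4-vector over a p-value grid, plus the worked example
  combos <- expand.grid(grid, grid, grid, grid)
  combos <- combos[apply(combos, 1, function(r) !is.unsorted(r)), ]
  for (i in seq_len(nrow(combos))) {
    p <- as.numeric(combos[i, ])
    expect_equal(fdr_twostage(p, 0.05)$reject, bky_brute(p, 0.05),
                 info = paste(p, collapse = ","))
  }
  # the worked example, expected set computed by the brute-force oracle
  p <- c(0.001, 0.02, 0.04, 0.8)
  expect_equal(fdr_twostage(p, 0.05)$reject, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(bky_brute(p, 0.05), c(TRUE, TRUE, TRUE, FALSE))
})

test_that("two-stage FDR matches brute force on random unsorted vectors
           and keeps q monotone in p", {
  set.seed(77)
  for (i in 1:50) {
    m <- sample(3:40, 1)
    p <- runif(m)^sample(1:3, 1)  # skew some toward small values
    res <- fdr_twostage(p, 0.05)
    expect_equal(res$reject, bky_brute(p, 0.05))
    expect_false(is.unsorted(res$q[order(p)]))
  }
})

test_that("two-stage FDR is calibrated under a complete null", {
  set.seed(42)
  n_rep <- 60; m <- 500
  any_rej <- vapply(seq_len(n_rep), function(i)
    any(fdr_twostage(runif(m), 0.05)$reject), logical(1L))
  # under the global null the FDP is 1{any rejection}; its mean must sit
  # near alpha
  expect_lte(mean(any_rej), 0.07 + 3 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("correlation screen calls a planted feature and respects the
           effect-size gate", {
  set.seed(5)
  n <- 100
  driver <- stats::setNames(rnorm(n), sprintf("s%03d", 1:n))
  scores <- t(vapply(1:50, function(i) rnorm(n), numeric(n)))
  rownames(scores) <- sprintf("null%02d", 1:50)
  colnames(scores) <- names(driver)
  scores <- rbind(scores,
                  planted = vector_with_exact_r(driver, 0.9, seed = 6),
                  weak = vector_with_exact_r(driver, 0.15, seed = 7))
  colnames(scores) <- names(driver)
  scr <- correlation_screen(driver, scores, alpha = 0.05, r_min = 0.2)
  rec <- scr$records
  expect_true(rec$significant[rec$feature == "planted"])
  expect_gt(rec$r[rec$feature == "planted"], 0)
  # exact r = 0.15 fails |R| > 0.2 regardless of its p-value
  expect_false(rec$significant[rec$feature == "weak"])
  expect_equal(rec$r[rec$feature == "weak"], 0.15, tolerance = 1e-12)
  expect_true(all(abs(rec$r) <= 1))
  # significance implies both gates
  expect_true(all(!rec$significant | (rec$q < 0.05 & abs(rec$r) > 0.2)))
})

test_that("screen is invariant to sample order and positive affine driver
           transforms", {
  set.seed(15)
  n <- 40
  driver <- stats::setNames(rnorm(n), sprintf("s%02d", 1:n))
  scores <- matrix(rnorm(5 * n), 5,
                   dimnames = list(sprintf("f%d", 1:5), names(driver)))
  a <- correlation_screen(driver, scores)
  perm <- sample(names(driver))
  b <- correlation_screen(driver[perm], scores[, perm])
  expect_equal(a$records, b$records)
  c_ <- correlation_screen(3 * driver + 11, scores)
  expect_equal(a$records$r, c_$records$r)
  expect_equal(a$records$p, c_$records$p)
})

test_that("null features produce false positives at no more than the
           nominal rate", {
  set.seed(99)
  n <- 60; m <- 200
  driver <- stats::setNames(rnorm(n), sprintf("s%02d", 1:n))
  scores <- matrix(rnorm(m * n), m,
                   dimnames = list(sprintf("f%03d", 1:m), names(driver)))
  scr <- correlation_screen(driver, scores, alpha = 0.05, r_min = 0.2)
  fp <- mean(scr$records$significant)
  expect_lte(fp, 0.05 + 3 * sqrt(0.05 * 0.95 / m))
})

test_that("constant features are dropped with a log entry", {
  set.seed(2)
  driver <- stats::setNames(rnorm(10), letters[1:10])
  scores <- rbind(flat = rep(1, 10), ok = rnorm(10))
  colnames(scores) <- names(driver)
  expect_message(scr <- correlation_screen(driver, scores), "dropped")
  expect_equal(scr$records$feature, "ok")
  expect_equal(scr$dropped, "flat@all")
})

test_that("PAS association screens pathways with FDR only by default", {
  set.seed(55)
  n <- 60
  driver <- stats::setNames(rnorm(n), sprintf("s%02d", 1:n))
  pas <- matrix(rnorm(n * 30), nrow = n,
                dimnames = list(names(driver), sprintf("PW%02d", 1:30)))
  pas[, "PW01"] <- vector_with_exact_r(driver, 0.8, seed = 56)
  res <- pas_association(pas, driver, alpha = 0.05)
  rec <- res$records
  expect_true(rec$significant[rec$feature == "PW01"])
  expect_gt(rec$r[rec$feature == "PW01"], 0)
  expect_lte(res$n_significant, 1L + ceiling(0.05 * 30) + 2L)
  expect_error(pas_association(pas, driver * 0 + 1), "driver is constant")
})

test_that("GMT signature reader round-trips simple sets", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("sigA\tdesc\tKIT\tMYC", "sigB\tdesc\tEPOR"), f)
  sets <- read_gmt(f)
  expect_equal(sets, list(sigA = c("KIT", "MYC"), sigB = "EPOR"))
  writeLines("broken\tonly-desc", f)
  expect_error(read_gmt(f), "line 1")
})
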