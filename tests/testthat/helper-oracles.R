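# Independent oracles, kept deliberately naive and separate from the
# implementations they check.

# Literal per-gene-loop evaluation of the pathway activation formula:
# PAL = sum_n NII*ARR*log(CNR) / sum_n NII*|ARR| over measured members.
pal_naive <- function(cnr_values, arr, log_base = 10) {
  num <- 0; den <- 0
  for (g in names(arr)) {
    if (!g %in% names(cnr_values)) next  # NII = 0 for unmeasured genes
    num <- num + arr[[g]] * log(cnr_values[[g]], base = log_base)
    den <- den + abs(arr[[g]])
  }
  if (den == 0) return(NA_real_)
  num / den
}

# Literal step-by-step two-stage (BKY) linear step-up: stage 1 BH at
# alpha' = alpha/(1+alpha); m0 = m - r1; stage 2 BH at alpha' * m / m0.
bky_brute <- function(p, alpha = 0.05) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  stepup <- function(level) {
    k <- 0
    for (i in seq_len(m)) if (ps[i] <= i * level / m) k <- i
    k
  }
  a1 <- alpha / (1 + alpha)
  r1 <- stepup(a1)
  m0 <- m - r1
  reject_sorted <- logical(m)
  if (m0 == 0) {
    reject_sorted[] <- TRUE
  } else {
    r2 <- stepup(a1 * m / m0)
    if (r2 > 0) reject_sorted[seq_len(r2)] <- TRUE
  }
  out <- logical(m)
  out[o] <- reject_sorted
  out
}

# Random pathway + expression instance for oracle-equivalence checks.
random_pal_instance <- function(n_genes = 30, n_members = 8, n_case = 3,
                                n_ctrl = 4) {
  genes <- sprintf("g%03d", seq_len(n_genes))
  expr <- matrix(10^rnorm(n_genes * (n_case + n_ctrl), mean = 2, sd = 0.5),
                 nrow = n_genes,
                 dimnames = list(genes, c(sprintf("c%02d", seq_len(n_case)),
                                          sprintf("n%02d", seq_len(n_ctrl)))))
  members <- sample(genes, n_members)
  arr <- stats::setNames(sample(c(-1, -0.5, 0, 0.5, 1), n_members,
                                replace = TRUE), members)
  if (all(arr == 0)) arr[1L] <- 1
  list(expr = expr,
       case = expr[, seq_len(n_case), drop = FALSE],
       control = expr[, n_case + seq_len(n_ctrl), drop = FALSE],
       pathway = pathway("RND", arr))
}

# Construct a vector with an exact sample Pearson correlation `rho` to x:
# combine the standardized x with an orthogonal unit-norm residual.
vector_with_exact_r <- function(x, rho, seed = 1) {
  set.seed(seed)
  n <- length(x)
  xc <- x - mean(x)
  repeat {
    e <- rnorm(n)
    e <- e - mean(e)
    e <- e - sum(e * xc) / sum(xc * xc) * xc
    if (sum(e^2) > 1e-12) break
  }
  rho * xc / sqrt(sum(xc^2)) + sqrt(1 - rho^2) * e / sqrt(sum(e^2))
}

tiny_collection <- function() {
  pathway_collection(list(
    pathway("ACT", c(A = 1, B = 1, C = 0.5), "signaling"),
    pathway("REP", c(D = -1, E = -1), "signaling"),
    pathway("MET", c(F = 1, G = -0.5), "metabolic")),
    source = "test")
}
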