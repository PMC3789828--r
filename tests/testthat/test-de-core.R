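# independent median-of-ratios oracle, straight from the definition
sf_oracle <- function(K) {
  geo <- apply(K, 1, function(x) exp(mean(log(x))))
  keep <- apply(K, 1, function(x) all(x > 0))
  raw <- apply(K, 2, function(col) median((col / geo)[keep]))
  raw / exp(mean(log(raw)))
}

test_that("size factors follow the median-of-ratios definition", {
  K <- matrix(c(10, 20, 30, 5, 40, 80, 120, 20), nrow = 4)
  dimnames(K) <- list(paste0("g", 1:4), c("s1", "s2"))
  expect_equal(estimate_size_factors(K), sf_oracle(K))

  # identical columns -> unit factors
  K2 <- cbind(s1 = c(3, 7, 11), s2 = c(3, 7, 11))
  rownames(K2) <- paste0("g", 1:3)
  expect_equal(unname(estimate_size_factors(K2)), c(1, 1))

  # doubled column: geometric-mean-1 convention forces (1/sqrt(2), sqrt(2))
  K3 <- cbind(s1 = c(10, 20, 30), s2 = c(20, 40, 60))
  rownames(K3) <- paste0("g", 1:3)
  expect_equal(unname(estimate_size_factors(K3)), c(1 / sqrt(2), sqrt(2)))

  # 4x3 toy against the brute-force oracle
  set.seed(11)
  K4 <- matrix(rpois(12, 60) + 1, nrow = 4,
               dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  expect_equal(estimate_size_factors(K4), sf_oracle(K4))

  K5 <- matrix(c(0, 5, 3, 0), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(estimate_size_factors(K5), "no gene has a positive count")
})

test_that("log2 fold change follows the pseudocounted mean-ratio definition", {
  # equal means in both conditions -> 0
  b <- toy_bundle(matrix(c(10, 10, 10, 10), nrow = 1))
  expect_equal(unname(log2_fold_change(b)), 0)

  # means 10 -> 20 with pseudocount 0 -> exactly 1 (equal depth by symmetry)
  K <- rbind(c(10, 10, 20, 20), c(10, 10, 20, 20), c(5, 5, 10, 10))
  b2 <- toy_bundle(K)
  cfg0 <- de_config(pseudocount = 0)
  sf <- estimate_size_factors(b2$counts)
  lfc <- log2_fold_change(b2, config = cfg0)
  kt <- normalized_counts(b2$counts, sf)
  expect_equal(unname(lfc),
               unname(log2(rowMeans(kt[, 3:4]) / rowMeans(kt[, 1:2]))))

  # all-zero gene stays finite at 0 with a positive pseudocount
  K3 <- rbind(c(0, 0, 0, 0), c(10, 12, 11, 9))
  expect_equal(unname(log2_fold_change(toy_bundle(K3)))[1], 0)
})

test_that("fold changes and p-values are invariant to sequencing depth", {
  set.seed(5)
  K <- matrix(rnbinom(200 * 6, mu = 80, size = 10), nrow = 200)
  b1 <- toy_bundle(K)
  K2 <- K
  K2[, 2] <- K[, 2] * 3L  # deeper library, same composition
  K2[, 5] <- K[, 5] * 2L
  b2 <- toy_bundle(K2)
  # ratio statistics are exactly depth-free without a pseudocount; the
  # pseudocount pins an absolute scale, leaving a small residual (see vignette)
  cfg0 <- de_config(pseudocount = 0)
  expect_equal(log2_fold_change(b1, config = cfg0),
               log2_fold_change(b2, config = cfg0), tolerance = 1e-12)
  expect_equal(log2_fold_change(b1), log2_fold_change(b2), tolerance = 0.01)
  expect_equal(nb_test(b1), nb_test(b2), tolerance = 0.05)
})

test_that("swapping condition labels negates every fold change", {
  set.seed(6)
  K <- matrix(rnbinom(100 * 6, mu = 60, size = 8), nrow = 100)
  b <- toy_bundle(K)
  swapped <- b
  swapped$meta$condition <- rev(swapped$meta$condition)
  expect_equal(log2_fold_change(b), -log2_fold_change(swapped), tolerance = 1e-12)
  expect_equal(nb_test(b), nb_test(swapped), tolerance = 1e-12)
})

test_that("NB test returns p = 1 for genes identical across all samples", {
  # equal-depth fixture: constant genes leave normalized counts constant too
  K <- rbind(c(7, 7, 7, 7, 7, 7), c(30, 30, 30, 30, 30, 30))
  b <- toy_bundle(K)
  expect_equal(unname(nb_test(b))[1], 1, tolerance = 1e-9)
  expect_equal(unname(nb_test(b, method = "exact"))[1], 1, tolerance = 1e-9)
})

test_that("NB test preconditions: two replicates per condition", {
  K <- matrix(c(5, 6, 8, 9), nrow = 1)
  cm <- toy_counts(K)
  meta <- data.frame(sample_id = colnames(cm$counts), species = "sp1",
                     condition = c("diapause", "developing", "developing",
                                   "developing"),
                     replicate = c(1, 1, 2, 3), assay = "mRNA",
                     stringsAsFactors = FALSE)
  b <- align_samples(cm, meta)
  expect_error(nb_test(b), ">= 2 replicates")
})

test_that("exact NB p-values match a brute-force enumeration of count splits", {
  # independent oracle: enumerate all (a, b) with a + b = total via the joint
  # probability table, normalizing over the diagonal
  exact_oracle <- function(kA, kB, sA, sB, alpha) {
    KS <- sum(kA) + sum(kB)
    SA <- sum(sA); SB <- sum(sB)
    q0 <- KS / (SA + SB)
    muA <- q0 * SA; muB <- q0 * SB
    sizeA <- muA^2 / (alpha * q0^2 * sum(sA^2))
    sizeB <- muB^2 / (alpha * q0^2 * sum(sB^2))
    diag_pr <- sapply(0:KS, function(a)
      dnbinom(a, mu = muA, size = sizeA) * dnbinom(KS - a, mu = muB, size = sizeB))
    obs <- diag_pr[sum(kA) + 1]
    sum(diag_pr[diag_pr <= obs * (1 + 1e-7)]) / sum(diag_pr)
  }
  for (case in list(list(kA = c(3, 5, 4), kB = c(9, 12, 10)),
                    list(kA = c(20, 18, 25), kB = c(21, 19, 23)),
                    list(kA = c(0, 1, 0), kB = c(4, 6, 5)))) {
    sA <- sB <- rep(1, 3)
    alpha <- 0.1
    got <- riboshift:::nb_exact_p(case$kA, case$kB, sA, sB, alpha)
    expect_equal(got, exact_oracle(case$kA, case$kB, sA, sB, alpha),
                 tolerance = 1e-6)
  }
})

test_that("NB test type-I error is calibrated on simulated null data", {
  b <- null_bundle(n_genes = 2000, dispersion = 0.1, seed = 42)
  p <- nb_test(b)
  expect_gte(mean(p <= 0.05), 0.03)
  expect_lte(mean(p <= 0.05), 0.07)
})

test_that("empirical FDR among flagged genes stays near nominal on a signal mix", {
  set.seed(19)
  n <- 2000; n_alt <- 200
  mu <- exp(rnorm(n, log(100), 1))
  fold <- c(rep(4, n_alt), rep(1, n - n_alt))
  mu_mat <- cbind(matrix(rep(mu, 3), n), matrix(rep(mu * fold, 3), n))
  K <- matrix(rnbinom(n * 6, mu = mu_mat, size = 1 / 0.05), n)
  b <- toy_bundle(K)
  fc <- fold_change_table(b, config = de_config(fdr_threshold = 0.1))
  hits <- which(fc$de_flag)
  false <- sum(hits > n_alt)
  expect_lte(false / max(1, length(hits)), 0.2)  # <= 2 x nominal
  expect_gt(length(hits), n_alt * 0.8)           # and real signal is found
})

test_that("BH adjustment equals the brute-force step-up definition", {
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    pmin(adj, 1)[order(o)]
  }
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(3)
  for (i in 1:25) {
    p <- runif(sample(1:200, 1))
    expect_equal(bh_fdr(p), bh_oracle(p))
  }
})

test_that("fold-change tables keep flags consistent", {
  set.seed(9)
  n <- 300
  mu <- exp(rnorm(n, log(40), 1.5))
  K <- matrix(rnbinom(n * 6, mu = rep(mu, 6), size = 20), n)
  K[1:30, 4:6] <- K[1:30, 4:6] * 8L
  fc <- fold_change_table(toy_bundle(K))
  expect_true(all(fc$de_flag[fc$de_flag] & fc$well_expressed[fc$de_flag]))
  expect_true(all(is.na(fc$fdr[!fc$well_expressed])))
  # BH monotone in p rank among well-expressed genes
  w <- fc[fc$well_expressed, ]
  o <- order(w$p_value)
  expect_true(all(diff(w$fdr[o]) >= -1e-12))
  # TSV writer round-trips
  path <- tempfile(fileext = ".tsv")
  write_fold_change_table(fc, path)
  back <- read.delim(path)
  expect_equal(back$lfc, fc$lfc, tolerance = 1e-6)
})
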