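two_species_map <- function(n, sp = c("spA", "spB")) {
  ga <- sprintf("a%03d", 1:n); gb <- sprintf("b%03d", 1:n)
  ortholog_map(pairwise = data.frame(species_a = sp[1], gene_a = ga,
                                     species_b = sp[2], gene_b = gb,
                                     stringsAsFactors = FALSE))
}

four_species_fc <- function(lfc_mat, sp = c("spA", "spB", "spC", "spD"),
                            we = TRUE) {
  n <- nrow(lfc_mat)
  tables <- lapply(seq_along(sp), function(j)
    fc_stub(lfc_mat[, j], gene_id = sprintf("%s_g%03d", sp[j], 1:n),
            species = sp[j], well_expressed = we))
  names(tables) <- sp
  map <- ortholog_map(fourway = as.data.frame(
    sapply(sp, function(s) sprintf("%s_g%03d", s, 1:n)), stringsAsFactors = FALSE))
  list(fc = tables, map = map)
}

test_that("ortholog fold-change correlations match rank and product-moment oracles", {
  map <- two_species_map(5)
  x <- c(0.3, -1.2, 2.0, 0.7, -0.1)
  y <- c(0.1, -0.9, 1.5, 1.0, -0.5)
  fa <- fc_stub(x, gene_id = sprintf("a%03d", 1:5), species = "spA")
  fb <- fc_stub(y, gene_id = sprintf("b%03d", 1:5), species = "spB")
  cc <- pairwise_fc_correlation(fa, fb, map)
  # brute-force rank formula: Pearson correlation of the ranks
  rank_oracle <- cor(rank(x), rank(y))
  expect_equal(cc$spearman, rank_oracle)
  expect_equal(cc$pearson, cor(x, y))
  expect_equal(cc$n_pairs, 5)

  same <- pairwise_fc_correlation(fa, fc_stub(x, gene_id = sprintf("b%03d", 1:5),
                                              species = "spB"), map)
  expect_equal(same$spearman, 1)
  expect_equal(same$pearson, 1)

  rev_ <- pairwise_fc_correlation(fa, fc_stub(-x, gene_id = sprintf("b%03d", 1:5),
                                              species = "spB"), map)
  expect_equal(rev_$spearman, -1)

  # well-expressed filtering applies in both species
  fb_some <- fc_stub(y, gene_id = sprintf("b%03d", 1:5), species = "spB",
                     well_expressed = c(TRUE, TRUE, TRUE, FALSE, TRUE))
  expect_equal(pairwise_fc_correlation(fa, fb_some, map)$n_pairs, 4)
  expect_error(pairwise_fc_correlation(
    fa, fc_stub(y, gene_id = sprintf("b%03d", 1:5), species = "spB",
                well_expressed = c(TRUE, TRUE, FALSE, FALSE, FALSE)), map),
    "fewer than 3")
})

test_that("four-way divergence matches the z-normalized pairwise-difference definition", {
  set.seed(14)
  lfc <- matrix(rnorm(4 * 50), ncol = 4)
  fx <- four_species_fc(lfc)
  div <- fourway_divergence(fx$fc, fx$map)
  # independent oracle: z-normalize each column, enumerate the 6 pairs
  z <- scale(lfc)
  oracle <- apply(z, 1, function(row) {
    pairs <- combn(4, 2)
    mean(abs(row[pairs[1, ]] - row[pairs[2, ]]))
  })
  expect_equal(unname(div$divergence), oracle)
  expect_true(all(div$divergence >= 0))

  # identical species -> divergence identically zero
  same <- four_species_fc(matrix(rep(rnorm(50), 4), ncol = 4))
  expect_equal(max(fourway_divergence(same$fc, same$map)$divergence), 0)

  # displacing one species' value for one group inflates only that group's
  # divergence, by the hand-enumerated 6-pair mean
  lfc2 <- lfc
  lfc2[1, 4] <- lfc2[1, 4] + 5
  z2 <- scale(lfc2)
  pairs <- combn(4, 2)
  expect_equal(unname(riboshift:::divergence_from_lfc(lfc2)[1]),
               mean(abs(z2[1, pairs[1, ]] - z2[1, pairs[2, ]])))
})

test_that("divergence is invariant to per-species affine rescaling", {
  set.seed(15)
  lfc <- matrix(rnorm(4 * 80), ncol = 4)
  base <- four_species_fc(lfc)
  shifted <- lfc
  shifted[, 2] <- 3 * lfc[, 2] + 7   # affine change in one species
  mod <- four_species_fc(shifted)
  expect_equal(fourway_divergence(base$fc, base$map)$divergence,
               fourway_divergence(mod$fc, mod$map)$divergence,
               tolerance = 1e-12)

  const <- four_species_fc(cbind(lfc[, 1:3], 5))
  expect_error(fourway_divergence(const$fc, const$map), "zero fold-change")
})

test_that("incomplete or poorly expressed groups are excluded from divergence", {
  set.seed(16)
  lfc <- matrix(rnorm(4 * 30), ncol = 4)
  we <- rep(TRUE, 30); we[4] <- FALSE
  tables <- four_species_fc(lfc)$fc
  tables$spB <- fc_stub(lfc[, 2], gene_id = sprintf("spB_g%03d", 1:30),
                        species = "spB", well_expressed = we)
  map <- four_species_fc(lfc)$map
  div <- fourway_divergence(tables, map)
  expect_equal(div$n_groups, 29)
  expect_false("4" %in% names(div$divergence))
})

test_that("shuffle control is deterministic and permutation mode preserves marginals", {
  set.seed(17)
  lfc_m <- matrix(rnorm(4 * 60), ncol = 4)
  lfc_r <- matrix(rnorm(4 * 60), ncol = 4)
  fm <- four_species_fc(lfc_m)
  fr <- four_species_fc(lfc_r)
  p1 <- divergence_shuffle_control(fm$fc, fr$fc, fm$map, n_shuffles = 5, seed = 99)
  p2 <- divergence_shuffle_control(fm$fc, fr$fc, fm$map, n_shuffles = 5, seed = 99)
  expect_identical(p1, p2)
  expect_length(p1, 5)
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_error(divergence_shuffle_control(fm$fc, fr$fc, fm$map, n_shuffles = 0),
               ">= 1")
})

test_that("PCA variance fractions, duplicated samples, and the eigen oracle", {
  set.seed(18)
  mat <- matrix(rnorm(3 * 4), nrow = 3,
                dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  pca <- pca_samples(mat)
  expect_equal(sum(pca$var_fraction), 1)

  # independent oracle: eigen-decomposition of the sample covariance
  x <- scale(t(mat), center = TRUE, scale = FALSE)
  eig <- eigen(cov(x))
  k <- min(dim(x)) - 1
  expect_equal(pca$var_fraction[1:k],
               (eig$values / sum(eig$values))[1:k], tolerance = 1e-10)
  for (j in 1:k)
    expect_equal(abs(unname(pca$loadings[, j])), abs(eig$vectors[, j]),
                 tolerance = 1e-8)

  # duplicated sample -> identical score rows
  mat2 <- cbind(mat, s5 = mat[, 2])
  pca2 <- pca_samples(mat2)
  expect_equal(pca2$scores["s5", ], pca2$scores["s2", ], tolerance = 1e-10)

  expect_error(pca_samples(matrix(1, 3, 3)), "constant")
})

test_that("high-loading gene extraction is thresholded and monotone", {
  set.seed(20)
  mat <- matrix(rnorm(50 * 6), nrow = 50,
                dimnames = list(sprintf("g%02d", 1:50), sprintf("s%d", 1:6)))
  mat["g01", ] <- mat["g01", ] + c(-8, -8, -8, 8, 8, 8)  # dominant gene
  pca <- pca_samples(mat)
  pca <- orient_component(pca, 1, c("s4", "s5", "s6"))
  hits2 <- high_loading_genes(pca, 1, k_sd = 2)
  hits3 <- high_loading_genes(pca, 1, k_sd = 3)
  expect_true("g01" %in% hits2)
  expect_true(all(hits3 %in% hits2))  # threshold monotonicity

  flat <- pca
  flat$loadings[, 1] <- 0.1
  expect_length(high_loading_genes(flat, 1), 0)
})
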