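# Cross-species statistics: ortholog fold-change correlation, four-way
# expression divergence with its shuffle null, and sample-level PCA.

#' Fold-change correlation between two species over ortholog pairs
#'
#' Pairs are taken from the pairwise links of an ortholog map; only pairs in
#' which both genes are well-expressed (in their own species) enter the
#' correlation.
#'
#' @param fc_a,fc_b Fold-change tables of the same assay for two species
#'   (species are read from the table attributes).
#' @param map An [ortholog_map()] with pairwise links covering the two species.
#' @return List with `spearman`, `pearson` and `n_pairs`.
#' @export
pairwise_fc_correlation <- function(fc_a, fc_b, map) {
  stopifnot(inherits(fc_a, "fold_change_table"),
            inherits(fc_b, "fold_change_table"),
            inherits(map, "ortholog_map"))
  sp_a <- attr(fc_a, "species"); sp_b <- attr(fc_b, "species")
  pw <- map$pairwise
  fwd <- pw$species_a == sp_a & pw$species_b == sp_b
  rev <- pw$species_a == sp_b & pw$species_b == sp_a
  ga <- c(pw$gene_a[fwd], pw$gene_b[rev])
  gb <- c(pw$gene_b[fwd], pw$gene_a[rev])
  if (length(ga) == 0L)
    stop("no pairwise ortholog links between '", sp_a, "' and '", sp_b, "'")
  ia <- match(ga, fc_a$gene_id); ib <- match(gb, fc_b$gene_id)
  keep <- !is.na(ia) & !is.na(ib)
  ia <- ia[keep]; ib <- ib[keep]
  keep <- fc_a$well_expressed[ia] & fc_b$well_expressed[ib] &
    is.finite(fc_a$lfc[ia]) & is.finite(fc_b$lfc[ib])
  ia <- ia[keep]; ib <- ib[keep]
  if (length(ia) < 3L)
    stop("fewer than 3 usable ortholog pairs between '", sp_a, "' and '", sp_b, "'")
  x <- fc_a$lfc[ia]; y <- fc_b$lfc[ib]
  list(spearman = stats::cor(x, y, method = "spearman"),
       pearson = stats::cor(x, y, method = "pearson"),
       n_pairs = length(x))
}

# Per-species lfc and well-expressed flags for the four-way gene slots.
fourway_lfc <- function(fc_tables, map) {
  species <- names(map$fourway)
  miss <- setdiff(species, names(fc_tables))
  if (length(miss) > 0L)
    stop("fold-change tables missing for species: ", paste(miss, collapse = ", "))
  lfc <- sapply(species, function(sp) {
    idx <- match(map$fourway[[sp]], fc_tables[[sp]]$gene_id)
    fc_tables[[sp]]$lfc[idx]
  })
  we <- sapply(species, function(sp) {
    idx <- match(map$fourway[[sp]], fc_tables[[sp]]$gene_id)
    ok <- fc_tables[[sp]]$well_expressed[idx]
    ok & !is.na(ok)
  })
  we[is.na(we)] <- FALSE
  we <- we & is.finite(lfc)
  list(lfc = lfc, we = we, complete = rowSums(we) == length(species))
}

# Core divergence computation on an lfc matrix (groups x species) already
# restricted to complete groups: z-normalize per species, mean absolute
# pairwise between-species difference per group.
divergence_from_lfc <- function(lfc) {
  sds <- apply(lfc, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero fold-change standard deviation within a species; ",
         "divergence is undefined")
  z <- scale(lfc)
  pairs <- utils::combn(ncol(z), 2L)
  rowMeans(abs(z[, pairs[1L, ], drop = FALSE] - z[, pairs[2L, ], drop = FALSE]))
}

#' Expression divergence within four-way ortholog groups
#'
#' Per species, log2 fold changes over the complete four-way gene set are
#' z-normalized (mean subtracted, divided by the standard deviation); per
#' group, the divergence is the mean over the unordered species pairs of the
#' absolute difference of the z-scores. A group is complete when all species'
#' genes are present and well-expressed.
#'
#' @param fc_tables Named list of fold-change tables (one per species of the
#'   map, same assay).
#' @param map An [ortholog_map()] with a four-way table.
#' @return List of class `divergence_result`: `divergence` (numeric, one value
#'   per complete group, row indices of the map as names), `n_groups`,
#'   `species`, `assay`.
#' @export
fourway_divergence <- function(fc_tables, map) {
  stopifnot(inherits(map, "ortholog_map"))
  if (nrow(map$fourway) < 2L) stop("need at least 2 four-way groups")
  fw <- fourway_lfc(fc_tables, map)
  keep <- which(fw$complete)
  if (length(keep) < 2L)
    stop("fewer than 2 four-way groups with complete, well-expressed fold changes")
  d <- divergence_from_lfc(fw$lfc[keep, , drop = FALSE])
  structure(list(divergence = stats::setNames(d, keep),
                 n_groups = length(keep),
                 species = names(map$fourway),
                 assay = attr(fc_tables[[1L]], "assay")),
            class = "divergence_result")
}

#' Compare mRNA and RPF divergence distributions
#'
#' Two-sample Kolmogorov-Smirnov test between the per-group divergences of the
#' two assays; smaller RPF divergence indicates stronger cross-species
#' conservation of translatome changes.
#'
#' @param div_mrna,div_rpf [fourway_divergence()] results.
#' @return List with `p_value`, `statistic`, `median_mrna`, `median_rpf`.
#' @export
compare_divergence <- function(div_mrna, div_rpf) {
  stopifnot(inherits(div_mrna, "divergence_result"),
            inherits(div_rpf, "divergence_result"))
  ks <- suppressWarnings(stats::ks.test(div_mrna$divergence, div_rpf$divergence))
  list(p_value = ks$p.value, statistic = unname(ks$statistic),
       median_mrna = stats::median(div_mrna$divergence),
       median_rpf = stats::median(div_rpf$divergence))
}

#' Shuffle control for the divergence comparison
#'
#' Rebuilds ortholog groups by randomly re-sampling each species' gene slot
#' (with replacement by default, matching the published control; a
#' without-replacement permutation mode is available), recomputes the mRNA and
#' RPF divergence distributions on the shuffled groups, and KS-compares them.
#'
#' The per-species z-normalization is computed once, over the groups complete
#' and well-expressed in both assays, before any shuffling: normalization is a
#' property of each species' observed fold changes, and shuffling only breaks
#' the ortholog pairing. The two assays are shuffled independently, so that
#' under exchangeable mRNA and RPF effects the returned p-values are
#' approximately uniform; re-standardizing within each shuffle, or reusing one
#' shuffle for both assays, would make the control conservative.
#'
#' @param fc_mrna_tables,fc_rpf_tables Named lists of fold-change tables per
#'   species for the two assays.
#' @param map An [ortholog_map()] with a four-way table.
#' @param n_shuffles Number of shuffles (>= 1).
#' @param seed Integer seed; the full p-value vector is reproducible.
#' @param replace Sample gene slots with replacement (`TRUE`, default) or
#'   permute without replacement.
#' @return Numeric vector of `n_shuffles` KS p-values.
#' @export
divergence_shuffle_control <- function(fc_mrna_tables, fc_rpf_tables, map,
                                       n_shuffles = 1000L, seed = 1L,
                                       replace = TRUE) {
  if (n_shuffles < 1L) stop("n_shuffles must be >= 1")
  fw_m <- fourway_lfc(fc_mrna_tables, map)
  fw_r <- fourway_lfc(fc_rpf_tables, map)
  common <- fw_m$complete & fw_r$complete
  if (sum(common) < 2L)
    stop("fewer than 2 groups complete in both assays")
  z_m <- scale(fw_m$lfc[common, , drop = FALSE])
  z_r <- scale(fw_r$lfc[common, , drop = FALSE])
  n <- sum(common)
  n_sp <- ncol(z_m)
  pairs <- utils::combn(n_sp, 2L)
  shuffled_div <- function(z) {
    idx <- vapply(seq_len(n_sp), function(j) sample.int(n, n, replace = replace),
                  integer(n))
    zs <- vapply(seq_len(n_sp), function(j) z[idx[, j], j], numeric(n))
    rowMeans(abs(zs[, pairs[1L, ], drop = FALSE] - zs[, pairs[2L, ], drop = FALSE]))
  }
  set.seed(seed)
  vapply(seq_len(n_shuffles), function(s) {
    dm <- shuffled_div(z_m)
    dr <- shuffled_div(z_r)
    suppressWarnings(stats::ks.test(dm, dr)$p.value)
  }, numeric(1L))
}

#' Expression matrix of four-way orthologs across samples
#'
#' Builds the input for [pca_samples()]: per species, counts are
#' depth-normalized and log2-transformed with a pseudocount; rows are four-way
#' ortholog groups (labelled `og_<row>`), columns are all species' samples.
#'
#' @param cms Named list (by species) of [count_matrix()] objects of one assay.
#' @param map An [ortholog_map()] with a four-way table covering the species.
#' @param config A [de_config()] (pseudocount is used).
#' @return Numeric matrix, groups x samples.
#' @export
fourway_expression_matrix <- function(cms, map, config = de_config()) {
  species <- names(map$fourway)
  miss <- setdiff(species, names(cms))
  if (length(miss) > 0L)
    stop("count matrices missing for species: ", paste(miss, collapse = ", "))
  blocks <- lapply(species, function(sp) {
    kt <- normalized_counts(cms[[sp]])
    idx <- match(map$fourway[[sp]], rownames(kt))
    if (anyNA(idx))
      stop("four-way genes absent from the ", sp, " count matrix: ",
           paste(utils::head(map$fourway[[sp]][is.na(idx)], 5L), collapse = ", "))
    log2(kt[idx, , drop = FALSE] + config$pseudocount)
  })
  out <- do.call(cbind, blocks)
  rownames(out) <- sprintf("og_%04d", seq_len(nrow(map$fourway)))
  out
}

#' Principal components of samples from an ortholog expression matrix
#'
#' Samples are the observations and ortholog groups the variables; groups are
#' centered (and optionally scaled to unit variance) before the
#' eigen-decomposition of the sample covariance.
#'
#' @param mat Numeric matrix, genes (or ortholog groups) x samples, typically
#'   from [fourway_expression_matrix()].
#' @param scale_mode Scale genes to unit variance before decomposition.
#' @return List of class `pca_result`: `scores` (samples x components),
#'   `loadings` (genes x components), `var_fraction` (sums to 1), `sdev`.
#' @export
pca_samples <- function(mat, scale_mode = FALSE) {
  if (nrow(mat) < 2L || ncol(mat) < 2L)
    stop("PCA needs at least 2 genes and 2 samples")
  v <- apply(mat, 1L, stats::var)
  if (all(v == 0)) stop("constant matrix: no variance to decompose")
  if (scale_mode && any(v == 0))
    stop("zero-variance rows cannot be scaled; drop them or use scale_mode = FALSE")
  pc <- stats::prcomp(t(mat), center = TRUE, scale. = scale_mode)
  structure(list(scores = pc$x, loadings = pc$rotation,
                 var_fraction = pc$sdev^2 / sum(pc$sdev^2), sdev = pc$sdev),
            class = "pca_result")
}

#' Genes exceptionally highly weighted on a principal component
#'
#' Returns the genes whose loading exceeds the mean loading of the component
#' by more than `k_sd` standard deviations. Principal-component signs are
#' arbitrary; orient the component first (e.g. so that developing samples
#' score higher) if the direction matters.
#'
#' @param pca A [pca_samples()] result.
#' @param component Component index.
#' @param k_sd Threshold in standard deviations of the loadings.
#' @return Character vector of gene (row) names.
#' @export
high_loading_genes <- function(pca, component = 1L, k_sd = 2) {
  stopifnot(inherits(pca, "pca_result"))
  if (component > ncol(pca$loadings)) stop("component ", component, " does not exist")
  l <- pca$loadings[, component]
  names(l)[l > mean(l) + k_sd * stats::sd(l)]
}

#' Orient a principal component so a sample group scores higher
#'
#' Flips the component's scores and loadings if the mean score of
#' `high_samples` is below the mean score of the remaining samples.
#'
#' @param pca A [pca_samples()] result.
#' @param component Component index.
#' @param high_samples Sample ids that should lie on the positive side.
#' @return The (possibly sign-flipped) `pca_result`.
#' @export
orient_component <- function(pca, component, high_samples) {
  stopifnot(inherits(pca, "pca_result"))
  s <- pca$scores[, component]
  hi <- rownames(pca$scores) %in% high_samples
  if (mean(s[hi]) < mean(s[!hi])) {
    pca$scores[, component] <- -pca$scores[, component]
    pca$loadings[, component] <- -pca$loadings[, component]
  }
  pca
}
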