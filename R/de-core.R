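# Normalization, fold changes, negative-binomial differential expression test,
# and BH-FDR. Every downstream statistic consumes the fold-change tables built
# here.

#' Differential-expression configuration
#'
#' @param fdr_threshold FDR cutoff for the differential-expression flag.
#' @param pseudocount Added to mean normalized counts before log2; keeps
#'   zero-count genes finite. The same value is used in both assays so that
#'   the identity `lfc_rpf = lfc_mrna + lfc_te` holds by construction.
#' @param well_expressed_min_mean Minimum mean normalized count (over all
#'   samples of a species/assay) for a gene to enter distribution statistics.
#' @param dispersion_floor Lower bound on the per-gene NB dispersion.
#' @param dispersion_mode How per-gene dispersions are moderated before
#'   testing: `"trend"` (fitted mean-dispersion trend, default; best
#'   type-I calibration with 3 replicates), `"max"` (maximum of the per-gene
#'   method-of-moments estimate and the trend; conservative), or `"gene"`
#'   (raw per-gene estimate; anti-conservative with few replicates).
#' @return A list of class `de_config`.
#' @export
de_config <- function(fdr_threshold = 0.1, pseudocount = 0.5,
                      well_expressed_min_mean = 10, dispersion_floor = 1e-8,
                      dispersion_mode = c("trend", "max", "gene")) {
  dispersion_mode <- match.arg(dispersion_mode)
  if (!(fdr_threshold > 0 && fdr_threshold < 1)) stop("fdr_threshold must be in (0,1)")
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  if (well_expressed_min_mean <= 0) stop("well_expressed_min_mean must be positive")
  if (dispersion_floor <= 0) stop("dispersion_floor must be positive")
  structure(list(fdr_threshold = fdr_threshold, pseudocount = pseudocount,
                 well_expressed_min_mean = well_expressed_min_mean,
                 dispersion_floor = dispersion_floor,
                 dispersion_mode = dispersion_mode),
            class = "de_config")
}

as_count_input <- function(x) {
  if (inherits(x, "count_matrix")) x$counts
  else if (inherits(x, "sample_bundle")) x$counts
  else if (is.matrix(x)) x
  else stop("expected a count_matrix, sample_bundle or matrix")
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over genes (restricted to
#' genes with a positive count in every sample) of the ratio of the sample's
#' count to the gene's geometric mean across samples. Factors are rescaled to
#' geometric mean 1, so normalized counts stay on the raw-count scale.
#'
#' @param x A [count_matrix()], sample bundle, or counts matrix (>= 2 samples).
#' @return Named vector of positive size factors with geometric mean 1.
#' @export
estimate_size_factors <- function(x) {
  K <- as_count_input(x)
  if (ncol(K) < 2L) stop("size factors need at least 2 samples")
  geo <- exp(rowMeans(log(K)))
  ok <- is.finite(geo) & geo > 0
  if (!any(ok))
    stop("no gene has a positive count in every sample; ",
         "filter genes or check the input")
  sf <- apply(K[ok, , drop = FALSE] / geo[ok], 2L, stats::median)
  sf <- sf / exp(mean(log(sf)))
  sf
}

#' Depth-normalized counts
#'
#' @param x A count matrix, bundle, or matrix.
#' @param size_factors Optional precomputed factors; estimated if `NULL`.
#' @return Matrix of counts divided by their sample's size factor.
#' @export
normalized_counts <- function(x, size_factors = NULL) {
  K <- as_count_input(x)
  if (is.null(size_factors)) size_factors <- estimate_size_factors(K)
  sweep(K, 2L, size_factors[colnames(K)], "/")
}

resolve_species <- function(bundle, species) {
  sp <- unique(bundle$meta$species)
  if (is.null(species)) {
    if (length(sp) > 1L)
      stop("bundle contains several species (", paste(sp, collapse = ", "),
           "); pass 'species'")
    return(sp)
  }
  if (!species %in% sp) stop("no samples for species '", species, "'")
  species
}

condition_means <- function(bundle, species, size_factors) {
  kt <- normalized_counts(bundle$counts, size_factors)
  lapply(stats::setNames(CONDITIONS, CONDITIONS), function(cond) {
    cols <- replicate_columns(bundle, species, cond)
    if (length(cols) == 0L) return(NULL)
    rowMeans(kt[, cols, drop = FALSE])
  })
}

#' Log2 fold change, developing versus diapause
#'
#' `lfc = log2((mean normalized developing + pseudocount) /
#'             (mean normalized diapause + pseudocount))`.
#'
#' @param bundle A sample bundle (one assay).
#' @param species Species to compute for; may be omitted for a single-species
#'   bundle.
#' @param config A [de_config()].
#' @return Named numeric vector of per-gene log2 fold changes.
#' @export
log2_fold_change <- function(bundle, species = NULL, config = de_config()) {
  stopifnot(inherits(bundle, "sample_bundle"))
  species <- resolve_species(bundle, species)
  b <- subset_bundle(bundle, species)
  sf <- estimate_size_factors(b$counts)
  cm <- condition_means(b, species, sf)
  if (is.null(cm$diapause) || is.null(cm$developing))
    stop("both conditions must be present for species '", species, "'")
  log2((cm$developing + config$pseudocount) / (cm$diapause + config$pseudocount))
}

# Per-gene method-of-moments dispersion and its trend over the mean.
# Returns list(gene = raw MoM estimates (may be negative), trend, final)
# where final applies the configured moderation mode and floor.
estimate_dispersions <- function(K, sf, cond, config) {
  kt <- sweep(K, 2L, sf, "/")
  groups <- split(seq_len(ncol(K)), cond)
  if (length(groups) < 2L) stop("need both conditions")
  if (any(lengths(groups) < 2L)) stop("need >= 2 replicates per condition")
  q0 <- rowMeans(kt)
  df_tot <- sum(lengths(groups) - 1L)
  vpool <- Reduce(`+`, lapply(groups, function(j) {
    (length(j) - 1L) * apply(kt[, j, drop = FALSE], 1L, stats::var)
  })) / df_tot
  xi <- mean(1 / sf)
  mom <- (vpool - q0 * xi) / q0^2   # raw: kept unclamped so the trend fit is unbiased
  ok <- is.finite(mom) & q0 > 0
  if (sum(ok) >= 10L) {
    fit <- stats::lm(mom[ok] ~ I(1 / q0[ok]))
    trend <- stats::coef(fit)[[1L]] + stats::coef(fit)[[2L]] / q0
  } else {
    trend <- rep(mean(mom[ok]), length(q0))
  }
  trend <- pmax(trend, config$dispersion_floor)
  final <- switch(config$dispersion_mode,
    trend = trend,
    max   = pmax(mom, trend, config$dispersion_floor),
    gene  = pmax(mom, config$dispersion_floor))
  final[!is.finite(final)] <- trend[!is.finite(final)]
  list(gene = mom, trend = trend, final = final)
}

#' Negative-binomial test for differential expression
#'
#' Tests, per gene, the null hypothesis of equal mean normalized expression in
#' the two conditions under a negative-binomial model with moderated
#' dispersion (per-gene method-of-moments estimate moderated through a fitted
#' mean-dispersion trend `alpha(mu) = a0 + a1/mu`; see [de_config()]).
#'
#' Two test statistics are available: `"wald"` (default) compares the
#' difference of condition means to its model standard error evaluated at the
#' pooled mean, suitable genome-wide; `"exact"` conditions on the total count
#' of each gene and sums the probabilities of all count splits no more likely
#' than the observed one (enumeration over the observed total, intended for
#' small-to-moderate counts).
#'
#' @param bundle A sample bundle (one assay).
#' @param species Species; may be omitted for a single-species bundle.
#' @param config A [de_config()].
#' @param method `"wald"` or `"exact"`.
#' @return Named vector of two-sided p-values.
#' @export
nb_test <- function(bundle, species = NULL, config = de_config(),
                    method = c("wald", "exact")) {
  method <- match.arg(method)
  stopifnot(inherits(bundle, "sample_bundle"))
  species <- resolve_species(bundle, species)
  b <- subset_bundle(bundle, species)
  cond <- b$meta$condition
  if (length(unique(cond)) < 2L)
    stop("both conditions must be present for species '", species, "'")
  if (any(table(cond) < 2L))
    stop("the negative-binomial test needs >= 2 replicates per condition")
  K <- b$counts
  sf <- estimate_size_factors(K)
  disp <- estimate_dispersions(K, sf, cond, config)$final
  A <- cond == "diapause"
  B <- cond == "developing"
  if (method == "wald") {
    kt <- sweep(K, 2L, sf, "/")
    nA <- sum(A); nB <- sum(B)
    qA <- rowMeans(kt[, A, drop = FALSE])
    qB <- rowMeans(kt[, B, drop = FALSE])
    q0 <- rowMeans(kt)
    v0 <- q0 * (mean(1 / sf[A]) / nA + mean(1 / sf[B]) / nB) +
      disp * q0^2 * (1 / nA + 1 / nB)
    z <- ifelse(v0 > 0, (qB - qA) / sqrt(v0), 0)
    p <- 2 * stats::pnorm(-abs(z))
  } else {
    p <- vapply(seq_len(nrow(K)), function(i) {
      nb_exact_p(K[i, A], K[i, B], sf[A], sf[B], disp[i])
    }, numeric(1L))
  }
  stats::setNames(p, rownames(K))
}

# Exact conditional NB test for one gene. Counts of each condition are summed;
# the sum is approximated as NB by moment matching, and the p-value is the
# total probability (conditional on the overall sum) of splits no more likely
# than the observed one.
nb_exact_p <- function(kA, kB, sA, sB, alpha) {
  KA <- sum(kA); KB <- sum(kB); KS <- KA + KB
  if (KS == 0) return(1)
  SA <- sum(sA); SB <- sum(sB)
  q0 <- KS / (SA + SB)
  muA <- q0 * SA; muB <- q0 * SB
  vA <- muA + alpha * q0^2 * sum(sA^2)
  vB <- muB + alpha * q0^2 * sum(sB^2)
  sizeA <- if (vA > muA) muA^2 / (vA - muA) else 1e8
  sizeB <- if (vB > muB) muB^2 / (vB - muB) else 1e8
  a <- 0:KS
  pr <- stats::dnbinom(a, mu = muA, size = sizeA) *
    stats::dnbinom(KS - a, mu = muB, size = sizeB)
  tot <- sum(pr)
  if (tot == 0) return(1)
  obs <- pr[KA + 1L]
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]) / tot)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up adjustment, monotone non-decreasing in p rank, capped at 1.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Vector of adjusted values in the input order.
#' @export
bh_fdr <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Per-gene fold-change table for one species and assay
#'
#' Combines normalization, fold change, NB test and BH-FDR. The FDR is
#' computed over well-expressed genes only (independent filtering); genes
#' below the expression floor keep their p-value but get `fdr = NA` and can
#' never be flagged differentially expressed.
#'
#' @param bundle A sample bundle (one assay).
#' @param species Species; may be omitted for a single-species bundle.
#' @param config A [de_config()].
#' @param method Test statistic passed to [nb_test()].
#' @return Data frame of class `fold_change_table` with columns `gene_id`,
#'   `base_mean`, `lfc`, `p_value`, `fdr`, `de_flag`, `well_expressed`;
#'   attributes `species`, `assay` and `config`.
#' @export
fold_change_table <- function(bundle, species = NULL, config = de_config(),
                              method = "wald") {
  species <- resolve_species(bundle, species)
  b <- subset_bundle(bundle, species)
  sf <- estimate_size_factors(b$counts)
  base_mean <- rowMeans(normalized_counts(b$counts, sf))
  lfc <- log2_fold_change(b, species, config)
  p <- nb_test(b, species, config, method = method)
  we <- base_mean >= config$well_expressed_min_mean
  fdr <- rep(NA_real_, length(p))
  fdr[we] <- bh_fdr(p[we])
  out <- data.frame(gene_id = rownames(b$counts), base_mean = base_mean,
                    lfc = lfc, p_value = p, fdr = fdr,
                    de_flag = !is.na(fdr) & fdr <= config$fdr_threshold,
                    well_expressed = we,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, species = species, assay = bundle$assay, config = config,
            class = c("fold_change_table", "data.frame"))
}

#' Write a fold-change table as TSV
#' @param fc A [fold_change_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fold_change_table <- function(fc, path) {
  utils::write.table(fc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
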