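# Genome-wide remodeling statistics: fold-change distribution summaries,
# mRNA-vs-RPF breadth comparison, and the replicate-variance control.

#' Fractions of well-expressed genes changing more than two-fold
#'
#' Strict inequality: a gene counts as up-regulated more than two-fold when
#' `lfc > 1` and down-regulated when `lfc < -1`; `|lfc| = 1` exactly counts as
#' neither.
#'
#' @param fc A [fold_change_table()].
#' @return List with `frac_up`, `frac_down` and `n` (number of well-expressed
#'   genes in the denominator).
#' @export
twofold_fractions <- function(fc) {
  stopifnot(inherits(fc, "fold_change_table"))
  lfc <- fc$lfc[fc$well_expressed]
  if (length(lfc) == 0L) stop("no well-expressed genes")
  list(frac_up = mean(lfc > 1), frac_down = mean(lfc < -1), n = length(lfc))
}

#' Compare the breadth of RPF and mRNA fold-change distributions
#'
#' Two-sample Kolmogorov-Smirnov test on absolute log2 fold changes, with the
#' ratio of median absolute fold changes (RPF over mRNA) as effect size. Both
#' vectors must cover the same well-expressed gene set; a broader RPF
#' distribution yields a small p-value and a ratio above 1.
#'
#' @param lfc_mrna,lfc_rpf Numeric vectors of log2 fold changes over the same
#'   genes (>= 20 each).
#' @return List with `p_value`, `statistic` (KS D) and `median_ratio`
#'   (`median |lfc_rpf| / median |lfc_mrna|`).
#' @export
breadth_test <- function(lfc_mrna, lfc_rpf) {
  if (length(lfc_mrna) != length(lfc_rpf))
    stop("fold-change vectors differ in length (", length(lfc_mrna), " vs ",
         length(lfc_rpf), ")")
  if (length(lfc_mrna) < 20L)
    stop("breadth test needs at least 20 genes")
  ks <- suppressWarnings(stats::ks.test(abs(lfc_rpf), abs(lfc_mrna)))
  list(p_value = ks$p.value, statistic = unname(ks$statistic),
       median_ratio = stats::median(abs(lfc_rpf)) / stats::median(abs(lfc_mrna)))
}

#' Between-replicate fold-change variability
#'
#' For each gene, the mean over within-condition replicate pairs of the
#' absolute log2 ratio of pseudocounted normalized counts -- the control that
#' between-replicate noise, unlike the condition contrast, is similar for RPF
#' and mRNA data. Pairs are pooled across the two conditions.
#'
#' @param bundle A sample bundle (one assay).
#' @param species Species; may be omitted for a single-species bundle.
#' @param config A [de_config()] (pseudocount is used).
#' @return Named numeric vector: per-gene mean pairwise absolute log2 ratio.
#' @export
replicate_variability <- function(bundle, species = NULL, config = de_config()) {
  stopifnot(inherits(bundle, "sample_bundle"))
  species <- resolve_species(bundle, species)
  b <- subset_bundle(bundle, species)
  kt <- normalized_counts(b$counts) + config$pseudocount
  total <- numeric(nrow(kt))
  n_pairs <- 0L
  for (cond in CONDITIONS) {
    cols <- replicate_columns(b, species, cond)
    if (length(cols) < 2L) next
    for (pair in utils::combn(cols, 2L, simplify = FALSE)) {
      total <- total + abs(log2(kt[, pair[1L]] / kt[, pair[2L]]))
      n_pairs <- n_pairs + 1L
    }
  }
  if (n_pairs == 0L) stop("replicate variability needs >= 2 replicates in a condition")
  stats::setNames(total / n_pairs, rownames(kt))
}

#' Remodeling summary for one species
#'
#' Bundles the two-fold fractions of both assays with the breadth test over
#' the genes well-expressed in both.
#'
#' @param fc_mrna,fc_rpf Fold-change tables of the two assays for one species.
#' @return List with per-assay `frac_up`/`frac_down`, the breadth test result,
#'   and the number of genes compared.
#' @export
remodel_summary <- function(fc_mrna, fc_rpf) {
  stopifnot(inherits(fc_mrna, "fold_change_table"),
            inherits(fc_rpf, "fold_change_table"))
  up_m <- twofold_fractions(fc_mrna)
  up_r <- twofold_fractions(fc_rpf)
  both <- intersect(fc_mrna$gene_id[fc_mrna$well_expressed],
                    fc_rpf$gene_id[fc_rpf$well_expressed])
  bt <- breadth_test(fc_mrna$lfc[match(both, fc_mrna$gene_id)],
                     fc_rpf$lfc[match(both, fc_rpf$gene_id)])
  list(mrna = up_m, rpf = up_r, breadth = bt, n_common = length(both))
}
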