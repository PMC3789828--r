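# Resource-allocation fractions and gene-set fold-change comparisons
# (ribosomal proteins, translation factors, PC1 genes, ...).

#' Fraction of ribosome footprints mapping to a gene set
#'
#' Computed from raw (unnormalized) counts: within each sample, the set's
#' counts divided by the sample total, then averaged within condition. The
#' per-sample fraction estimates the share of translating ribosomes engaged on
#' the set's transcripts.
#'
#' @param cm A [count_matrix()] (normally RPF counts).
#' @param set A [gene_set()] whose genes are all present in the matrix.
#' @param meta Sample metadata covering the matrix columns.
#' @return List of class `allocation_result`: `per_sample` (named fractions)
#'   and `per_condition` (mean fraction per condition), plus `set`.
#' @export
footprint_fraction <- function(cm, set, meta) {
  stopifnot(inherits(cm, "count_matrix"), inherits(set, "gene_set"))
  missing <- setdiff(set$gene_ids, rownames(cm$counts))
  if (length(missing) > 0L)
    stop("gene set '", set$name, "' has genes absent from the count matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  totals <- colSums(cm$counts)
  if (any(totals == 0)) stop("sample with zero total count")
  frac <- colSums(cm$counts[set$gene_ids, , drop = FALSE]) / totals
  meta <- validate_sample_meta(meta)
  meta <- meta[match(names(frac), meta$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id)) stop("metadata missing for some samples")
  per_cond <- vapply(CONDITIONS, function(cd)
    mean(frac[meta$condition == cd]), numeric(1L))
  structure(list(per_sample = frac,
                 per_condition = per_cond,
                 set = set$name),
            class = "allocation_result")
}

#' Compare a gene set's fold changes between assays
#'
#' Paired two-tailed t-test on `lfc_rpf - lfc_mrna` over the set's genes
#' (unpaired Welch test available), with per-assay summaries on both the log2
#' and linear scales. Because the averaging scale is ambiguous for skewed fold
#' changes, both the mean of per-gene linear fold changes (`mean_fold`) and
#' the fold change of the mean lfc (`fold_of_mean`) are reported; `mean_fold`
#' is the headline figure.
#'
#' @param fc_mrna,fc_rpf Fold-change tables for one species.
#' @param set A [gene_set()] with at least 3 genes present in both tables.
#' @param paired Use the gene-matched paired test (default) or unpaired.
#' @return List of class `geneset_comparison`: `set`, `n`, `t_statistic`,
#'   `p_value`, `mean_diff` (mean lfc_rpf - mean lfc_mrna), `zero_variance`,
#'   and per-assay summaries `mrna` and `rpf` (each with `mean_lfc`,
#'   `median_lfc`, `iqr_lfc`, `mean_fold`, `fold_of_mean`).
#' @export
geneset_fc_compare <- function(fc_mrna, fc_rpf, set, paired = TRUE) {
  stopifnot(inherits(fc_mrna, "fold_change_table"),
            inherits(fc_rpf, "fold_change_table"),
            inherits(set, "gene_set"))
  im <- match(set$gene_ids, fc_mrna$gene_id)
  ir <- match(set$gene_ids, fc_rpf$gene_id)
  keep <- !is.na(im) & !is.na(ir) &
    is.finite(fc_mrna$lfc[im]) & is.finite(fc_rpf$lfc[ir])
  if (sum(keep) < 3L)
    stop("gene set '", set$name, "' has fewer than 3 genes with fold changes ",
         "in both assays")
  m <- fc_mrna$lfc[im[keep]]
  r <- fc_rpf$lfc[ir[keep]]
  d <- r - m
  zero_var <- if (paired) stats::sd(d) < 1e-12 else
    (stats::sd(m) < 1e-12 && stats::sd(r) < 1e-12)
  if (zero_var) {
    # t.test cannot handle essentially-constant differences; a nonzero shift
    # with zero variance is overwhelming evidence, a zero shift is none
    tt <- if (abs(mean(d)) > 1e-12) list(statistic = sign(mean(d)) * Inf, p.value = 0)
          else list(statistic = 0, p.value = 1)
  } else if (paired) {
    tt <- stats::t.test(r, m, paired = TRUE)
  } else {
    tt <- stats::t.test(r, m)
  }
  summarize <- function(x) list(mean_lfc = mean(x), median_lfc = stats::median(x),
                                iqr_lfc = stats::IQR(x),
                                mean_fold = mean(2^x), fold_of_mean = 2^mean(x))
  structure(list(set = set$name, n = sum(keep),
                 t_statistic = unname(tt$statistic), p_value = tt$p.value,
                 mean_diff = mean(d), zero_variance = zero_var,
                 mrna = summarize(m), rpf = summarize(r)),
            class = "geneset_comparison")
}

#' @export
print.geneset_comparison <- function(x, ...) {
  cat(sprintf(
    "gene set '%s' (n = %d): mean fold mRNA %.2f, RPF %.2f; t = %.2f, p = %.3g%s\n",
    x$set, x$n, x$mrna$mean_fold, x$rpf$mean_fold, x$t_statistic, x$p_value,
    if (x$zero_variance) " [zero variance]" else ""))
  invisible(x)
}
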