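# Translation-efficiency changes, concordant/discordant classification with an
# exact binomial test, and the translational-component score.

#' Translation-efficiency changes
#'
#' Since translation efficiency is the ratio of RPF to mRNA abundance, its
#' log2 change is `lfc_te = lfc_rpf - lfc_mrna`, exactly, when both tables use
#' the same pseudocount convention.
#'
#' @param fc_mrna,fc_rpf Fold-change tables over the same gene universe.
#' @return Data frame of class `te_change_table` with columns `gene_id`,
#'   `lfc_mrna`, `lfc_rpf`, `lfc_te`.
#' @export
te_change <- function(fc_mrna, fc_rpf) {
  stopifnot(inherits(fc_mrna, "fold_change_table"),
            inherits(fc_rpf, "fold_change_table"))
  extra <- c(setdiff(fc_mrna$gene_id, fc_rpf$gene_id),
             setdiff(fc_rpf$gene_id, fc_mrna$gene_id))
  if (length(extra) > 0L)
    stop("gene universes differ between the two assays: ",
         paste(utils::head(extra, 10L), collapse = ", "),
         if (length(extra) > 10L) sprintf(" (and %d more)", length(extra) - 10L))
  idx <- match(fc_mrna$gene_id, fc_rpf$gene_id)
  out <- data.frame(gene_id = fc_mrna$gene_id,
                    lfc_mrna = fc_mrna$lfc,
                    lfc_rpf = fc_rpf$lfc[idx],
                    stringsAsFactors = FALSE)
  out$lfc_te <- out$lfc_rpf - out$lfc_mrna
  structure(out, species = attr(fc_mrna, "species"),
            class = c("te_change_table", "data.frame"))
}

#' Genes differentially expressed in both assays
#'
#' @param fc_mrna,fc_rpf Fold-change tables for one species.
#' @return Character vector of gene ids flagged in both tables.
#' @export
joint_de_genes <- function(fc_mrna, fc_rpf) {
  intersect(fc_mrna$gene_id[fc_mrna$de_flag], fc_rpf$gene_id[fc_rpf$de_flag])
}

#' Classify concordant and discordant expression changes
#'
#' A gene's change is *concordant* when the RPF fold change has the same sign
#' as, and strictly greater magnitude than, the mRNA fold change (translation
#' amplifies the mRNA-level change), and *discordant* when the RPF change is
#' of strictly lesser magnitude or of opposite sign (translation opposes it).
#' Exact magnitude ties are excluded and reported. Genes with `lfc_mrna = 0`
#' are classified by the RPF change alone: concordant when `|lfc_rpf| > 0`,
#' tie otherwise.
#'
#' @param te A [te_change()] table.
#' @param genes Genes to classify, normally [joint_de_genes()].
#' @return List of class `concordance_result`: `table` (gene_id, label),
#'   `n_concordant`, `n_discordant`, `n_ties`, `ratio`
#'   (concordant:discordant; `Inf` when nothing is discordant) and `p_value`
#'   from [concordance_binomial()].
#' @export
classify_concordance <- function(te, genes) {
  stopifnot(inherits(te, "te_change_table"))
  missing <- setdiff(genes, te$gene_id)
  if (length(missing) > 0L)
    stop("genes not in the table: ", paste(utils::head(missing, 10L), collapse = ", "))
  idx <- match(genes, te$gene_id)
  m <- te$lfc_mrna[idx]
  r <- te$lfc_rpf[idx]
  label <- ifelse(m == 0 & r == 0, "excluded_tie",
           ifelse(m == 0, "concordant",
           ifelse(sign(r) != sign(m), "discordant",
           ifelse(abs(r) > abs(m), "concordant",
           ifelse(abs(r) < abs(m), "discordant", "excluded_tie")))))
  n_c <- sum(label == "concordant")
  n_d <- sum(label == "discordant")
  structure(list(
    table = data.frame(gene_id = genes, label = label, stringsAsFactors = FALSE),
    n_concordant = n_c, n_discordant = n_d,
    n_ties = sum(label == "excluded_tie"),
    ratio = if (n_d > 0L) n_c / n_d else Inf,
    p_value = if (n_c + n_d >= 1L) concordance_binomial(n_c, n_d) else NA_real_),
    class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("concordance: %d concordant, %d discordant (%d ties), ratio %.2f:1, binomial p = %.3g\n",
              x$n_concordant, x$n_discordant, x$n_ties, x$ratio, x$p_value))
  invisible(x)
}

#' Exact two-sided binomial test for concordance counts
#'
#' Null hypothesis: concordant and discordant changes are equally likely
#' (p = 0.5). Two-sided by summing the probabilities of all outcomes no more
#' likely than the observed one.
#'
#' @param n_conc,n_disc Non-negative integer counts with `n_conc + n_disc >= 1`.
#' @return The exact two-sided p-value.
#' @export
concordance_binomial <- function(n_conc, n_disc) {
  if (n_conc < 0 || n_disc < 0 || n_conc != floor(n_conc) || n_disc != floor(n_disc))
    stop("counts must be non-negative integers")
  n <- n_conc + n_disc
  if (n < 1) stop("at least one classified gene is required")
  pr <- stats::dbinom(0:n, n, 0.5)
  obs <- pr[n_conc + 1L]
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}

#' Translational component of regulation
#'
#' For each differentially expressed gene, the score
#' `tc_score = log2(|lfc_te| / |lfc_mrna|)` and the bounded fraction
#' `tc_fraction = |lfc_te| / (|lfc_te| + |lfc_mrna|)` quantify how much of the
#' RPF-level change is attributable to translation-efficiency change versus
#' mRNA-abundance change. Categories: `mostly_translational`
#' (`tc_fraction > 0.75`), `mostly_mrna` (`< 0.25`), `mixed` otherwise
#' (boundaries fall into `mixed`; the cutoffs correspond to
#' `tc_score = +/- log2(3)`). Genes with `lfc_mrna = 0` get fraction 1, genes
#' with `lfc_te = 0` get fraction 0; genes with both components zero are
#' flagged `undefined` and excluded from category fractions. Genes whose mRNA
#' and RPF changes disagree in sign are still scored on magnitudes and carry
#' `discordant_flag`.
#'
#' @param te A [te_change()] table.
#' @param genes Genes to score, normally those differentially expressed in the
#'   RPF data.
#' @return Data frame of class `tc_table`: `gene_id`, `lfc_mrna`, `lfc_te`,
#'   `tc_score`, `tc_fraction`, `category`, `discordant_flag`, `undefined`.
#' @export
translational_component <- function(te, genes) {
  stopifnot(inherits(te, "te_change_table"))
  missing <- setdiff(genes, te$gene_id)
  if (length(missing) > 0L)
    stop("genes not in the table: ", paste(utils::head(missing, 10L), collapse = ", "))
  idx <- match(genes, te$gene_id)
  am <- abs(te$lfc_mrna[idx])
  at <- abs(te$lfc_te[idx])
  undefined <- am == 0 & at == 0
  frac <- ifelse(undefined, NA_real_, at / (at + am))
  score <- ifelse(undefined, NA_real_, log2(at / am))
  cat_ <- ifelse(undefined, NA_character_,
          ifelse(frac > 0.75, "mostly_translational",
          ifelse(frac < 0.25, "mostly_mrna", "mixed")))
  structure(data.frame(
    gene_id = genes,
    lfc_mrna = te$lfc_mrna[idx], lfc_te = te$lfc_te[idx],
    tc_score = score, tc_fraction = frac, category = cat_,
    discordant_flag = te$lfc_mrna[idx] * te$lfc_rpf[idx] < 0,
    undefined = undefined,
    stringsAsFactors = FALSE),
    species = attr(te, "species"),
    class = c("tc_table", "data.frame"))
}

#' Category fractions of the translational component
#'
#' @param tc A [translational_component()] table.
#' @return Named vector of the fractions of `mostly_mrna`, `mixed` and
#'   `mostly_translational` genes (over categorized genes; sums to 1).
#' @export
tc_category_fractions <- function(tc) {
  stopifnot(inherits(tc, "tc_table"))
  categorized <- tc$category[!is.na(tc$category)]
  if (length(categorized) == 0L) stop("no categorized genes")
  lv <- c("mostly_mrna", "mixed", "mostly_translational")
  tab <- table(factor(categorized, levels = lv))
  stats::setNames(as.vector(tab) / length(categorized), lv)
}
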