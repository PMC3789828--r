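# End-to-end orchestration: fold-change tables per species and assay, then
# every downstream statistic, collected into one structured report.

REPORT_SCHEMA_VERSION <- 1L

bundles_by_assay <- function(ds) {
  per_species <- function(cms) {
    out <- lapply(names(cms), function(sp)
      align_samples(cms[[sp]], ds$meta[ds$meta$species == sp, , drop = FALSE]))
    stats::setNames(out, names(cms))
  }
  list(mrna = per_species(ds$mrna), rpf = per_species(ds$rpf))
}

#' Run the full analysis pipeline
#'
#' Executes, per species: normalization, fold changes and the NB test for both
#' assays; remodeling statistics (two-fold fractions, breadth test, replicate
#' variability); concordance classification with binomial test; and the
#' translational-component categories. Across species (when at least two
#' species and a four-way map are available): pairwise ortholog fold-change
#' correlations, four-way divergence with KS comparison and optional shuffle
#' control, and PCA of the four-way expression matrices. For each configured
#' gene set: fold-change comparison between assays and RPF allocation
#' fractions.
#'
#' @param ds A [simulate_dataset()] result or a dataset loaded with
#'   [load_dataset()].
#' @param config A [de_config()].
#' @param n_shuffles Shuffle-control iterations (0 disables the control).
#' @param seed Seed for the shuffle control (the only random stage).
#' @param out_dir If non-`NULL`, per-stage TSVs and the JSON report are
#'   written here.
#' @return The report, a nested list; stages skipped for structural reasons
#'   are recorded under `skipped` with the reason.
#' @export
run_all <- function(ds, config = de_config(), n_shuffles = 0L, seed = 1L,
                    out_dir = NULL) {
  stopifnot(inherits(ds, "sim_dataset") || is.list(ds))
  species <- unique(ds$meta$species)
  report <- list(schema_version = REPORT_SCHEMA_VERSION, seed = seed,
                 species = species, skipped = list())

  bundles <- bundles_by_assay(ds)
  fc <- list(mrna = list(), rpf = list())
  for (sp in species) {
    fc$mrna[[sp]] <- fold_change_table(bundles$mrna[[sp]], sp, config)
    fc$rpf[[sp]] <- fold_change_table(bundles$rpf[[sp]], sp, config)
  }

  report$remodeling <- lapply(stats::setNames(species, species), function(sp) {
    rs <- remodel_summary(fc$mrna[[sp]], fc$rpf[[sp]])
    rv_m <- replicate_variability(bundles$mrna[[sp]], sp, config)
    rv_r <- replicate_variability(bundles$rpf[[sp]], sp, config)
    list(mrna_frac_up = rs$mrna$frac_up, mrna_frac_down = rs$mrna$frac_down,
         rpf_frac_up = rs$rpf$frac_up, rpf_frac_down = rs$rpf$frac_down,
         breadth_p = rs$breadth$p_value, breadth_median_ratio = rs$breadth$median_ratio,
         replicate_var_median_mrna = stats::median(rv_m),
         replicate_var_median_rpf = stats::median(rv_r),
         n_well_expressed_mrna = rs$mrna$n, n_well_expressed_rpf = rs$rpf$n)
  })

  report$concordance <- lapply(stats::setNames(species, species), function(sp) {
    te <- te_change(fc$mrna[[sp]], fc$rpf[[sp]])
    joint <- joint_de_genes(fc$mrna[[sp]], fc$rpf[[sp]])
    cc <- classify_concordance(te, joint)
    tc <- translational_component(te, fc$rpf[[sp]]$gene_id[fc$rpf[[sp]]$de_flag])
    list(n_concordant = cc$n_concordant, n_discordant = cc$n_discordant,
         n_ties = cc$n_ties, ratio = cc$ratio, binomial_p = cc$p_value,
         tc_fractions = as.list(tc_category_fractions(tc)),
         n_rpf_de = sum(fc$rpf[[sp]]$de_flag))
  })

  if (length(species) >= 2L && nrow(ds$map$fourway) >= 2L) {
    pair_list <- utils::combn(species, 2L, simplify = FALSE)
    report$correlations <- lapply(pair_list, function(pr) {
      out <- list(species_a = pr[1L], species_b = pr[2L])
      for (a in c("mrna", "rpf")) {
        cc <- pairwise_fc_correlation(fc[[a]][[pr[1L]]], fc[[a]][[pr[2L]]], ds$map)
        out[[paste0("spearman_", a)]] <- cc$spearman
        out[[paste0("pearson_", a)]] <- cc$pearson
        out[[paste0("n_pairs_", a)]] <- cc$n_pairs
      }
      out
    })
    div_m <- fourway_divergence(fc$mrna, ds$map)
    div_r <- fourway_divergence(fc$rpf, ds$map)
    report$divergence <- compare_divergence(div_m, div_r)
    report$divergence$n_groups_mrna <- div_m$n_groups
    report$divergence$n_groups_rpf <- div_r$n_groups
    if (n_shuffles > 0L) {
      pvals <- divergence_shuffle_control(fc$mrna, fc$rpf, ds$map,
                                          n_shuffles = n_shuffles, seed = seed)
      report$shuffle_control <- list(
        n_shuffles = n_shuffles,
        p_median = stats::median(pvals),
        frac_below_0.05 = mean(pvals < 0.05))
    }
    report$pca <- lapply(stats::setNames(c("mrna", "rpf"), c("mrna", "rpf")),
                         function(a) {
      mat <- fourway_expression_matrix(ds[[a]], ds$map, config)
      pca <- pca_samples(mat)
      dev_samples <- ds$meta$sample_id[ds$meta$condition == "developing" &
                                         tolower(ds$meta$assay) == a]
      pca <- orient_component(pca, 1L, dev_samples)
      s1 <- pca$scores[, 1L]
      dev <- rownames(pca$scores) %in% dev_samples
      list(var_fraction_pc1 = pca$var_fraction[1L],
           var_fraction_pc2 = pca$var_fraction[2L],
           pc1_separation_margin = min(s1[dev]) - max(s1[!dev]),
           pc1_separates_conditions = min(s1[dev]) > max(s1[!dev]))
    })
  } else {
    report$skipped$cross_species <-
      "needs at least 2 species and a four-way ortholog map"
  }

  if (length(ds$gene_sets) > 0L) {
    report$gene_sets <- lapply(ds$gene_sets, function(per_sp) {
      lapply(per_sp[intersect(names(per_sp), species)], function(set) {
        cmp <- geneset_fc_compare(fc$mrna[[set$species]], fc$rpf[[set$species]], set)
        alloc <- footprint_fraction(ds$rpf[[set$species]], set, ds$meta)
        list(n = cmp$n, p_value = cmp$p_value, mean_diff = cmp$mean_diff,
             mean_fold_mrna = cmp$mrna$mean_fold, mean_fold_rpf = cmp$rpf$mean_fold,
             allocation_diapause = unname(alloc$per_condition[["diapause"]]),
             allocation_developing = unname(alloc$per_condition[["developing"]]))
      })
    })
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (a in c("mrna", "rpf"))
      for (sp in species)
        write_fold_change_table(fc[[a]][[sp]],
                                file.path(out_dir, sprintf("fc_%s_%s.tsv", a, sp)))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}
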