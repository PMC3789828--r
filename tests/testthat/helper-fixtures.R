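# Fixtures are built in code; nothing is read from disk except files the
# tests themselves write to tempdir().

toy_counts <- function(body, genes = NULL, samples = NULL, assay = "mRNA") {
  K <- as.matrix(body)
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(K)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(K)))
  dimnames(K) <- list(genes, samples)
  count_matrix(K, assay)
}

# one-species bundle: first half of columns diapause, second half developing
toy_bundle <- function(body, assay = "mRNA", species = "sp1",
                       genes = NULL, samples = NULL) {
  cm <- toy_counts(body, genes, samples, assay)
  ids <- colnames(cm$counts)
  n <- length(ids) %/% 2L
  meta <- data.frame(sample_id = ids, species = species,
                     condition = rep(c("diapause", "developing"), each = n),
                     replicate = rep(seq_len(n), 2L), assay = assay,
                     stringsAsFactors = FALSE)
  align_samples(cm, meta)
}

# hand-built fold-change table for testing downstream operations in isolation
fc_stub <- function(lfc, gene_id = sprintf("g%03d", seq_along(lfc)),
                    well_expressed = TRUE, de_flag = FALSE,
                    base_mean = 100, species = "sp1", assay = "mRNA") {
  df <- data.frame(gene_id = gene_id, base_mean = base_mean, lfc = lfc,
                   p_value = NA_real_, fdr = NA_real_,
                   de_flag = rep_len(de_flag, length(lfc)),
                   well_expressed = rep_len(well_expressed, length(lfc)),
                   stringsAsFactors = FALSE)
  structure(df, species = species, assay = assay,
            class = c("fold_change_table", "data.frame"))
}

# scaled-down simulation keeping the preset's statistical structure
small_sim_config <- function(seed = 1L, n_genes = 600L, ...) {
  sim_config(n_genes = n_genes, library_size = n_genes * 150,
             geneset_effects = list(
               ribosomal_proteins = list(n = 20L, mrna_lfc = 1.0, te_lfc = 2.6,
                                         baseline_boost = 5.5),
               translation_factors = list(n = 15L, mrna_lfc = 1.0, te_lfc = 1.3,
                                          baseline_boost = 3.0)),
             seed = seed, ...)
}

# null dataset for calibration checks: equal means, shared dispersion
null_bundle <- function(n_genes = 2000L, n_rep = 3L, dispersion = 0.1,
                        assay = "mRNA", seed = 42L) {
  set.seed(seed)
  mu <- exp(rnorm(n_genes, log(100), 1))
  K <- matrix(rnbinom(n_genes * 2L * n_rep, mu = rep(mu, 2L * n_rep),
                      size = 1 / dispersion), nrow = n_genes)
  toy_bundle(K, assay = assay)
}
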