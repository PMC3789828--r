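test_that("count matrix TSV round-trip preserves counts, ids and order", {
  body <- matrix(c(1, 2, 0, 5, 10, 10), nrow = 3, byrow = TRUE)
  cm <- toy_counts(body)
  expect_equal(sum(cm$counts), 28)

  path <- tempfile(fileext = ".tsv")
  write_count_matrix(cm, path)
  back <- read_count_matrix(path, "mRNA")
  expect_identical(back$counts, cm$counts)
  expect_identical(rownames(back$counts), rownames(cm$counts))
  expect_identical(colnames(back$counts), colnames(cm$counts))

  # comment lines and the gene_id header are part of the dialect
  lines <- readLines(path)
  writeLines(c("# a comment", lines), path)
  expect_identical(read_count_matrix(path, "mRNA")$counts, cm$counts)
})

test_that("invalid count files are rejected with the offending cell located", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "gA\t3\t-1", "gB\t0\t2"), path)
  expect_error(read_count_matrix(path, "RPF"), "gA.*s2.*-1")
  writeLines(c("gene_id\ts1\ts2", "gA\t3\t1.5", "gB\t0\t2"), path)
  expect_error(read_count_matrix(path, "RPF"), "gA.*s2")
  writeLines(c("id\ts1\ts2", "gA\t3\t1"), path)
  expect_error(read_count_matrix(path, "RPF"), "gene_id")
})

test_that("count matrix invariants are enforced", {
  K <- matrix(1:4, 2, dimnames = list(c("a", "a"), c("s1", "s2")))
  expect_error(count_matrix(K, "RPF"), "duplicate gene id")
  K <- matrix(1:4, 2, dimnames = list(c("a", "b"), c("s1", "s1")))
  expect_error(count_matrix(K, "RPF"), "duplicate sample id")
  K <- matrix(c(1, -1, 2, 3), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(count_matrix(K, "RPF"), "invalid count")
  K <- matrix(1:2, 2, dimnames = list(c("a", "b"), "s1"))
  expect_error(count_matrix(K, "RPF"), "at least 1 gene and 2 samples")
})

test_that("ortholog map readers validate group structure", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("spA\tspB\tspC\tspD",
               "a1\tb1\tc1\td1",
               "a2\tb2\tc2\td2"), path)
  map <- read_ortholog_map(path)
  expect_equal(nrow(map$fourway), 2)
  expect_named(map$fourway, c("spA", "spB", "spC", "spD"))

  writeLines(c("spA\tspB\tspC\tspD",
               "a1\tb1\tc1\td1",
               "a1\tb2\tc2\td2"), path)
  expect_error(read_ortholog_map(path), "more than one ortholog group.*spA")

  # empty file -> empty, valid map
  writeLines("spA\tspB\tspC\tspD", path)
  empty <- read_ortholog_map(path)
  expect_equal(nrow(empty$fourway), 0)
})

test_that("pairwise ortholog tables round-trip through both dialects", {
  two_col <- tempfile(fileext = ".tsv")
  writeLines(c("spA\tspB", "a1\tb1", "a2\tb2"), two_col)
  map <- read_ortholog_map(two_col)
  expect_equal(nrow(map$pairwise), 2)
  expect_equal(map$pairwise$species_a, c("spA", "spA"))

  out <- tempfile(fileext = ".tsv")
  write_ortholog_map(map, pairwise_path = out)
  expect_equal(read_ortholog_map(out)$pairwise, map$pairwise)
})

test_that("align_samples binds metadata, errors on orphans, warns on extras", {
  K <- matrix(rpois(12 * 8, 50), nrow = 8)
  dimnames(K) <- list(sprintf("g%d", 1:8), sprintf("s%d", 1:12))
  cm <- count_matrix(K, "RPF")
  meta <- data.frame(sample_id = sprintf("s%d", 1:12), species = "sp1",
                     condition = rep(c("diapause", "developing"), each = 6),
                     replicate = rep(1:6, 2), assay = "RPF",
                     stringsAsFactors = FALSE)
  b <- align_samples(cm, meta)
  expect_s3_class(b, "sample_bundle")
  expect_length(replicate_columns(b, "sp1", "diapause"), 6)
  expect_length(replicate_columns(b, "sp1", "developing"), 6)

  expect_error(align_samples(cm, meta[-3, ]), "without metadata.*s3")
  meta_extra <- rbind(meta, data.frame(sample_id = "ghost", species = "sp1",
                                       condition = "diapause", replicate = 7,
                                       assay = "RPF"))
  expect_warning(b2 <- align_samples(cm, meta_extra), "ghost")
  expect_identical(b2$meta$sample_id, colnames(K))

  meta_wrong <- meta; meta_wrong$assay <- "mRNA"
  expect_error(align_samples(cm, meta_wrong), "without metadata")
})

test_that("sample metadata validation catches duplicates and bad levels", {
  meta <- data.frame(sample_id = c("s1", "s2"), species = "sp1",
                     condition = c("diapause", "fed"), replicate = 1:2,
                     assay = "RPF", stringsAsFactors = FALSE)
  expect_error(align_samples(toy_counts(matrix(1:4, 2)), meta), "condition")
  meta$condition <- "diapause"
  meta$sample_id <- c("s1", "s1")
  expect_error(validate_sample_meta <- riboshift:::validate_sample_meta(meta),
               "duplicate sample_id")
})

test_that("gene sets read and write one id per line", {
  path <- tempfile(fileext = ".txt")
  writeLines(c("# ribosomal proteins", "gA", "gB", "", "gC"), path)
  set <- read_gene_set(path, species = "sp1", name = "ribo")
  expect_identical(set$gene_ids, c("gA", "gB", "gC"))
  out <- tempfile(fileext = ".txt")
  write_gene_set(set, out)
  expect_identical(read_gene_set(out, "sp1", "ribo")$gene_ids, set$gene_ids)
  expect_error(gene_set("empty", "sp1", character()), "empty")
})
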