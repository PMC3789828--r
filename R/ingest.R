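# Data model and I/O: count matrices, sample metadata, ortholog maps, gene sets.
#
# File dialect (all readers/writers): TSV, UTF-8, '#'-prefixed comment lines
# skipped, first column of a count matrix headed by the literal "gene_id".
# Gene identifiers are opaque strings; no species-prefix parsing.

ASSAYS <- c("RPF", "mRNA")
CONDITIONS <- c("diapause", "developing")

#' Construct a validated count matrix
#'
#' A count matrix holds gene x sample non-negative integer counts for a single
#' assay (ribosome-protected fragments or mRNA-seq).
#'
#' @param counts Numeric matrix of non-negative integers with unique rownames
#'   (gene ids) and unique colnames (sample ids). At least 1 gene and 2 samples.
#' @param assay One of `"RPF"` or `"mRNA"`.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (integer-valued matrix) and `assay`.
#' @export
count_matrix <- function(counts, assay) {
  assay <- match.arg(assay, ASSAYS)
  if (!is.matrix(counts)) stop("'counts' must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("'counts' must have gene ids as rownames and sample ids as colnames")
  if (nrow(counts) < 1L || ncol(counts) < 2L)
    stop("a count matrix needs at least 1 gene and 2 samples")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene id: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample id: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  bad <- which(!is.finite(counts) | counts < 0 | counts != floor(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("invalid count at gene '%s', sample '%s': %s",
                 rownames(counts)[bad[1L, 1L]], colnames(counts)[bad[1L, 2L]],
                 format(counts[bad[1L, , drop = FALSE]])))
  storage.mode(counts) <- "double"  # counts can exceed .Machine$integer.max in sums
  structure(list(counts = counts, assay = assay), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples, assay = %s, total = %s\n",
              nrow(x$counts), ncol(x$counts), x$assay,
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' Read a count matrix from a TSV file
#'
#' Expects a header row `gene_id<TAB>sample1<TAB>...`, one row per gene and an
#' integer body. Lines starting with `#` are skipped.
#'
#' @param path Path to the TSV file.
#' @param assay One of `"RPF"` or `"mRNA"`.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(path, assay) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("count matrix file needs a gene_id column plus samples: ", path)
  if (names(df)[1L] != "gene_id")
    stop("first column of a count matrix must be headed 'gene_id', got '",
         names(df)[1L], "': ", path)
  genes <- df[[1L]]
  body <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(is.na(num) | num < 0 | num != floor(num), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-integer or negative count at gene '%s', sample '%s': '%s'",
                 genes[bad[1L, 1L]], colnames(body)[bad[1L, 2L]],
                 body[bad[1L, , drop = FALSE]]))
  dimnames(num) <- list(genes, colnames(body))
  count_matrix(num, assay)
}

#' Write a count matrix to a TSV file
#'
#' Mirrors [read_count_matrix()]: write-then-read preserves counts, ids and
#' ordering exactly.
#'
#' @param cm A [count_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(cm, path) {
  stopifnot(inherits(cm, "count_matrix"))
  df <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_sample_meta <- function(meta) {
  need <- c("sample_id", "species", "condition", "replicate", "assay")
  miss <- setdiff(need, names(meta))
  if (length(miss) > 0L) stop("sample metadata lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample_id in metadata: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", "))
  if (!all(meta$condition %in% CONDITIONS))
    stop("condition must be one of: ", paste(CONDITIONS, collapse = ", "))
  if (!all(meta$assay %in% ASSAYS))
    stop("assay must be one of: ", paste(ASSAYS, collapse = ", "))
  if (!all(meta$replicate == floor(meta$replicate) & meta$replicate >= 1))
    stop("replicate must be a positive integer")
  key <- interaction(meta$species, meta$condition, meta$replicate, meta$assay, drop = TRUE)
  if (anyDuplicated(key))
    stop("duplicate (species, condition, replicate, assay) combination in metadata")
  meta
}

#' Read a sample metadata table from a TSV file
#'
#' Columns: `sample_id`, `species`, `condition` (`diapause`/`developing`),
#' `replicate` (positive integer), `assay` (`RPF`/`mRNA`).
#'
#' @param path Path to the TSV file.
#' @return A validated data frame.
#' @export
read_sample_meta <- function(path) {
  meta <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  validate_sample_meta(meta)
}

#' Write a sample metadata table
#' @param meta Sample metadata data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_meta <- function(meta, path) {
  utils::write.table(validate_sample_meta(meta), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a validated ortholog map
#'
#' @param fourway Data frame with one column per species; each row is a
#'   four-way (more generally, n-way) ortholog group with exactly one gene per
#'   species. `NULL` for none.
#' @param pairwise Data frame with columns `species_a`, `gene_a`, `species_b`,
#'   `gene_b` giving pairwise ortholog links (stored once per unordered pair,
#'   treated as symmetric). `NULL` for none.
#' @return An object of class `ortholog_map`.
#' @export
ortholog_map <- function(fourway = NULL, pairwise = NULL) {
  if (!is.null(fourway)) {
    fourway <- as.data.frame(fourway, stringsAsFactors = FALSE)
    if (ncol(fourway) < 2L) stop("a four-way table needs at least two species columns")
    for (sp in names(fourway)) {
      col <- fourway[[sp]]
      if (anyDuplicated(col))
        stop("gene appears in more than one ortholog group for species '", sp, "': ",
             paste(unique(col[duplicated(col)]), collapse = ", "))
      if (any(is.na(col) | col == ""))
        stop("missing gene in four-way table for species '", sp, "'")
    }
  } else {
    fourway <- data.frame()
  }
  if (!is.null(pairwise)) {
    pairwise <- as.data.frame(pairwise, stringsAsFactors = FALSE)
    need <- c("species_a", "gene_a", "species_b", "gene_b")
    if (!all(need %in% names(pairwise)))
      stop("pairwise table needs columns: ", paste(need, collapse = ", "))
  } else {
    pairwise <- data.frame(species_a = character(), gene_a = character(),
                           species_b = character(), gene_b = character(),
                           stringsAsFactors = FALSE)
  }
  structure(list(fourway = fourway, pairwise = pairwise), class = "ortholog_map")
}

#' @export
print.ortholog_map <- function(x, ...) {
  cat(sprintf("ortholog_map: %d four-way groups over {%s}; %d pairwise links\n",
              nrow(x$fourway), paste(names(x$fourway), collapse = ", "),
              nrow(x$pairwise)))
  invisible(x)
}

#' Read ortholog tables
#'
#' Each file is a TSV whose columns are species names. A file with exactly two
#' columns is read as pairwise links; a file with three or more columns is
#' read as n-way ortholog groups. Several pairwise files may be combined with
#' at most one group file. An empty file yields an empty (valid) map.
#'
#' @param paths Character vector of file paths.
#' @return An [ortholog_map()].
#' @export
read_ortholog_map <- function(paths) {
  fourway <- NULL
  pw <- list()
  for (path in paths) {
    df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                            stringsAsFactors = FALSE, colClasses = "character")
    if (nrow(df) == 0L) next
    if (identical(names(df), c("species_a", "gene_a", "species_b", "gene_b"))) {
      pw[[length(pw) + 1L]] <- df
    } else if (ncol(df) == 2L) {
      pw[[length(pw) + 1L]] <- data.frame(
        species_a = names(df)[1L], gene_a = df[[1L]],
        species_b = names(df)[2L], gene_b = df[[2L]],
        stringsAsFactors = FALSE)
    } else {
      if (!is.null(fourway)) stop("more than one n-way ortholog table supplied")
      fourway <- df
    }
  }
  ortholog_map(fourway = fourway,
               pairwise = if (length(pw) > 0L) do.call(rbind, pw) else NULL)
}

#' Write an ortholog map
#'
#' Writes the n-way group table to `fourway_path` and/or the pairwise link
#' table to `pairwise_path`, mirroring [read_ortholog_map()].
#'
#' @param map An [ortholog_map()].
#' @param fourway_path,pairwise_path Output paths (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_ortholog_map <- function(map, fourway_path = NULL, pairwise_path = NULL) {
  stopifnot(inherits(map, "ortholog_map"))
  if (!is.null(fourway_path))
    utils::write.table(map$fourway, fourway_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(pairwise_path)) {
    pw <- map$pairwise
    # two-column dialect, one file per species pair, is read back by
    # read_ortholog_map; for a single mixed table keep the 4-column layout
    utils::write.table(pw, pairwise_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(c(fourway_path, pairwise_path))
}

#' Construct a gene set
#'
#' @param name Set name (e.g. `"ribosomal_proteins"`).
#' @param species Species identifier the ids belong to.
#' @param gene_ids Non-empty character vector of gene ids (de-duplicated).
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(name, species, gene_ids) {
  gene_ids <- unique(as.character(gene_ids))
  if (length(gene_ids) == 0L) stop("gene set '", name, "' is empty")
  structure(list(name = name, species = species, gene_ids = gene_ids),
            class = "gene_set")
}

#' Read a gene set from a one-id-per-line text file
#'
#' @param path File with one gene id per line; `#` comments and blank lines
#'   are skipped.
#' @param name Set name; defaults to the file name without extension.
#' @param species Species identifier.
#' @return A [gene_set()].
#' @export
read_gene_set <- function(path, species, name = sub("\\.[^.]*$", "", basename(path))) {
  ids <- readLines(path)
  ids <- trimws(ids)
  ids <- ids[nzchar(ids) & !startsWith(ids, "#")]
  gene_set(name, species, ids)
}

#' Write a gene set to a one-id-per-line text file
#' @param set A [gene_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_set <- function(set, path) {
  stopifnot(inherits(set, "gene_set"))
  writeLines(set$gene_ids, path)
  invisible(path)
}

#' Bind a count matrix to its sample metadata
#'
#' Validates that every sample column has exactly one metadata row of matching
#' assay. Samples present in the counts but absent from the metadata are a
#' hard error; metadata rows with no matching sample column are dropped with a
#' warning and the bundle is built from the intersection.
#'
#' @param cm A [count_matrix()].
#' @param meta Sample metadata data frame (see [read_sample_meta()]).
#' @return An object of class `sample_bundle`: list with `counts` (matrix),
#'   `meta` (rows aligned to columns of `counts`) and `assay`.
#' @export
align_samples <- function(cm, meta) {
  stopifnot(inherits(cm, "count_matrix"))
  meta <- validate_sample_meta(meta)
  meta <- meta[meta$assay == cm$assay, , drop = FALSE]
  samples <- colnames(cm$counts)
  orphan <- setdiff(samples, meta$sample_id)
  if (length(orphan) > 0L)
    stop("samples without metadata (assay ", cm$assay, "): ",
         paste(orphan, collapse = ", "))
  extra <- setdiff(meta$sample_id, samples)
  if (length(extra) > 0L) {
    warning("metadata rows without matching sample dropped: ",
            paste(extra, collapse = ", "))
    meta <- meta[meta$sample_id %in% samples, , drop = FALSE]
  }
  meta <- meta[match(samples, meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(counts = cm$counts, meta = meta, assay = cm$assay),
            class = "sample_bundle")
}

#' @export
print.sample_bundle <- function(x, ...) {
  cat(sprintf("sample_bundle: %d genes, %d samples, assay = %s, species = {%s}\n",
              nrow(x$counts), ncol(x$counts), x$assay,
              paste(unique(x$meta$species), collapse = ", ")))
  invisible(x)
}

#' Replicate columns for one (species, condition)
#'
#' @param bundle A [align_samples()] bundle.
#' @param species Species identifier.
#' @param condition `"diapause"` or `"developing"`.
#' @return Character vector of sample ids.
#' @export
replicate_columns <- function(bundle, species, condition) {
  stopifnot(inherits(bundle, "sample_bundle"))
  condition <- match.arg(condition, CONDITIONS)
  bundle$meta$sample_id[bundle$meta$species == species &
                          bundle$meta$condition == condition]
}

#' Restrict a bundle to one species
#' @param bundle A sample bundle.
#' @param species Species identifier present in the bundle.
#' @return A `sample_bundle` containing only that species' samples.
#' @export
subset_bundle <- function(bundle, species) {
  stopifnot(inherits(bundle, "sample_bundle"))
  keep <- bundle$meta$species == species
  if (!any(keep)) stop("no samples for species '", species, "'")
  structure(list(counts = bundle$counts[, bundle$meta$sample_id[keep], drop = FALSE],
                 meta = bundle$meta[keep, , drop = FALSE],
                 assay = bundle$assay),
            class = "sample_bundle")
}
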