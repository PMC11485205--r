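# Readers and writers for the plain-text interchange formats: expression
# TSV/MTX, sample metadata, weighted edge lists, GMT gene-set collections,
# and ranked-list (.rnk) export for preranked enrichment tools.

#' Read / write an expression matrix as TSV
#'
#' Genes in rows, samples in columns; first column holds gene identifiers,
#' header row holds sample identifiers.
#'
#' @param path file path.
#' @param space value space of the matrix (see [expression_matrix()]).
#' @return `read_expression_tsv()` returns an expression matrix.
#' @export
read_expression_tsv <- function(path, space = "normalized_log") {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  genes <- as.character(dt[[1]])
  m <- as.matrix(dt[, -1, drop = FALSE])
  rownames(m) <- genes
  expression_matrix(m, space)
}

#' @rdname read_expression_tsv
#' @param x expression matrix to write.
#' @export
write_expression_tsv <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Read an expression matrix in MatrixMarket format
#'
#' Expects `<path>` (MTX), plus sidecar files `<prefix>.genes.txt` and
#' `<prefix>.samples.txt` (one identifier per line) where `<prefix>` is the
#' MTX path without its extension.
#'
#' @inheritParams read_expression_tsv
#' @export
read_expression_mtx <- function(path, space = "counts") {
  prefix <- sub("\\.mtx$", "", path)
  m <- as.matrix(Matrix::readMM(path))
  rownames(m) <- readLines(paste0(prefix, ".genes.txt"))
  colnames(m) <- readLines(paste0(prefix, ".samples.txt"))
  expression_matrix(m, space)
}

#' Read / write sample metadata TSV
#'
#' Required columns: `sample_id`, `age_group`, `age_numeric`; further columns
#' (tissue, covariates) pass through untouched.
#'
#' @param path file path.
#' @export
read_metadata_tsv <- function(path) {
  meta <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  check_metadata(meta)
  meta
}

#' @rdname read_metadata_tsv
#' @param meta metadata data.frame.
#' @export
write_metadata_tsv <- function(meta, path) {
  data.table::fwrite(meta, path, sep = "\t")
  invisible(path)
}

#' Read / write a regulatory model as a weighted edge-list TSV
#'
#' Columns `predictor`, `target`, `weight`, tab separated with a header.
#'
#' @param path file path.
#' @export
read_model_tsv <- function(path) {
  regulatory_model(
    data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE))
}

#' @rdname read_model_tsv
#' @param model a `regulatory_model`.
#' @export
write_model_tsv <- function(model, path) {
  data.table::fwrite(as.data.frame(model), path, sep = "\t")
  invisible(path)
}

#' Read / write GMT gene-set collections
#'
#' Standard GMT: one set per line, `name <tab> description <tab> gene...`.
#' Empty sets are dropped with a warning.
#'
#' @param path file path.
#' @return a named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    genes <- unique(parts[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) {
      warning("empty gene set '", parts[1], "' dropped")
      next
    }
    sets[[parts[1]]] <- genes
  }
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param description optional per-set description (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Export a ranked gene list (.rnk)
#'
#' Two tab-separated columns (gene, score), no header, sorted by decreasing
#' score - the input format of preranked gene-set enrichment tools.
#'
#' @param scores named numeric vector (e.g. predictability slopes).
#' @param path file path.
#' @export
write_rnk <- function(scores, path) {
  scores <- scores[is.finite(scores)]
  scores <- sort(scores, decreasing = TRUE)
  data.table::fwrite(data.frame(gene = names(scores), score = scores),
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}
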