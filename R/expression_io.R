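#' Read a gene x sample expression matrix from TSV
#'
#' The expected layout is a header line `gene_id<TAB>sample1<TAB>...` and one
#' row per gene, cells holding non-negative FPKM values. Row and column order
#' of the file are preserved. Gene identifiers are treated as opaque strings;
#' pass a `normalize_ids` function (e.g. one that strips Ensembl version
#' suffixes) to transform them on the way in — off by default.
#'
#' @param path Path to a TSV file.
#' @param normalize_ids Optional function applied to the gene identifier
#'   column; must preserve length and uniqueness.
#' @return A numeric matrix with genes as rownames and samples as colnames.
#' @export
read_expression_matrix <- function(path, normalize_ids = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("expression matrix file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L) {
    stop("malformed expression matrix: need >= 1 gene row and >= 1 sample column",
         call. = FALSE)
  }
  gene_ids <- df[[1L]]
  sample_ids <- colnames(df)[-1L]
  if (!is.null(normalize_ids)) gene_ids <- normalize_ids(gene_ids)
  if (anyDuplicated(gene_ids)) {
    stop(sprintf("duplicate gene id: %s",
                 gene_ids[duplicated(gene_ids)][1L]), call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop(sprintf("duplicate sample id: %s",
                 sample_ids[duplicated(sample_ids)][1L]), call. = FALSE)
  }
  vals <- matrix(NA_real_, nrow = nrow(df), ncol = length(sample_ids),
                 dimnames = list(gene_ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    col <- suppressWarnings(as.numeric(df[[j + 1L]]))
    bad <- which(is.na(col))
    if (length(bad)) {
      stop(sprintf("non-numeric or missing value for gene '%s', sample '%s'",
                   gene_ids[bad[1L]], sample_ids[j]), call. = FALSE)
    }
    neg <- which(col < 0)
    if (length(neg)) {
      stop(sprintf("negative value (%s) for gene '%s', sample '%s'",
                   df[[j + 1L]][neg[1L]], gene_ids[neg[1L]], sample_ids[j]),
           call. = FALSE)
    }
    vals[, j] <- col
  }
  vals
}

#' Write an expression matrix to TSV
#'
#' Values are written with full double precision so that
#' `read_expression_matrix(write_expression_matrix(m))` reproduces `m`
#' exactly. Use [write_table()] for human-facing report tables.
#'
#' @param m Numeric gene x sample (or gene x tissue) matrix with dimnames.
#' @param path Output path.
#' @param id_column Header of the identifier column (default `"gene_id"`).
#' @return Invisibly, `path`.
#' @export
write_expression_matrix <- function(m, path, id_column = "gene_id") {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c(id_column, colnames(m)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], sprintf("%.17g", m[i, ])), collapse = "\t")
  }, character(1L))
  writeLines(body, con)
  invisible(path)
}

#' Read a sample-to-tissue manifest from TSV
#'
#' Expected columns: `sample_id` and `tissue`, one row per sample.
#'
#' @param path Path to a TSV file.
#' @return A data.frame with character columns `sample_id` and `tissue`.
#' @export
read_sample_manifest <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("manifest file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  if (!all(c("sample_id", "tissue") %in% colnames(df))) {
    stop("manifest must have columns 'sample_id' and 'tissue'", call. = FALSE)
  }
  df <- df[, c("sample_id", "tissue")]
  validate_manifest(df)
  df
}

validate_manifest <- function(manifest) {
  stopifnot(is.data.frame(manifest),
            all(c("sample_id", "tissue") %in% colnames(manifest)))
  if (anyDuplicated(manifest$sample_id)) {
    stop(sprintf("duplicate sample id in manifest: %s",
                 manifest$sample_id[duplicated(manifest$sample_id)][1L]),
         call. = FALSE)
  }
  if (any(!nzchar(manifest$tissue))) {
    stop("manifest contains an empty tissue label", call. = FALSE)
  }
  invisible(manifest)
}

#' Aggregate replicate samples to per-tissue expression values
#'
#' Collapses a gene x sample matrix to a gene x tissue matrix by taking the
#' arithmetic mean of each gene's FPKM over the samples assigned to a tissue.
#' Tissue columns are ordered lexicographically so downstream outputs are
#' deterministic regardless of sample order.
#'
#' @param m Numeric gene x sample matrix (e.g. from
#'   [read_expression_matrix()]).
#' @param manifest Data.frame with columns `sample_id`, `tissue` covering
#'   every column of `m`. Manifest rows for samples absent from the matrix
#'   are ignored with a warning.
#' @return A numeric gene x tissue matrix.
#' @export
#' @examples
#' m <- matrix(c(1, 3, 2, 4), nrow = 1,
#'             dimnames = list("g1", c("s1", "s2", "s3", "s4")))
#' man <- data.frame(sample_id = c("s1", "s2", "s3", "s4"),
#'                   tissue = c("liver", "liver", "lung", "lung"))
#' aggregate_to_tissue(m, man)
aggregate_to_tissue <- function(m, manifest) {
  stopifnot(is.matrix(m), is.numeric(m), !is.null(colnames(m)))
  validate_manifest(manifest)
  missing <- setdiff(colnames(m), manifest$sample_id)
  if (length(missing)) {
    stop(sprintf("sample(s) missing from manifest: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  extra <- setdiff(manifest$sample_id, colnames(m))
  if (length(extra)) {
    warning(sprintf("manifest sample(s) absent from matrix, ignored: %s",
                    paste(extra, collapse = ", ")), call. = FALSE)
    manifest <- manifest[manifest$sample_id %in% colnames(m), , drop = FALSE]
  }
  tissues <- sort(unique(manifest$tissue))
  out <- matrix(0, nrow = nrow(m), ncol = length(tissues),
                dimnames = list(rownames(m), tissues))
  for (t in tissues) {
    cols <- manifest$sample_id[manifest$tissue == t]
    out[, t] <- rowMeans(m[, cols, drop = FALSE])
  }
  out
}

#' Write a report table to TSV
#'
#' Generic TSV writer for the package's tabular outputs: header row, tab
#' separator, no quoting, numeric (double) columns rendered with four decimal
#' places, rows in the order given.
#'
#' @param rows A data.frame; all rows share the schema.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  out <- rows
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.4f", out[[j]])
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
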