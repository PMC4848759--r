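#' Classify an atlas from files
#'
#' Reads a replicate-level expression matrix and its sample manifest,
#' aggregates to tissue means, classifies every gene and writes
#' `classification.tsv`, `summary.tsv` (Table-style category counts and
#' integer percentages) and `per_tissue_elevated.tsv` to `out_dir`.
#'
#' @param matrix_path Matrix TSV (`gene_id<TAB>sample...`).
#' @param manifest_path Manifest TSV (`sample_id<TAB>tissue`).
#' @param out_dir Output directory (created if needed).
#' @param params [classifier_params()].
#' @return Invisibly, a list with `classes` and `summary`.
#' @export
run_classify <- function(matrix_path, manifest_path, out_dir,
                         params = classifier_params()) {
  m <- read_expression_matrix(matrix_path)
  manifest <- read_sample_manifest(manifest_path)
  em <- aggregate_to_tissue(m, manifest)
  classes <- classify_matrix(em, params)
  smry <- summarize_classification(classes)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_classification(classes, file.path(out_dir, "classification.tsv"))
  cat_df <- smry$categories
  cat_df$definition <- category_definitions()[cat_df$category]
  write_table(cat_df[, c("category", "definition", "count", "percent")],
              file.path(out_dir, "summary.tsv"))
  write_table(smry$per_tissue, file.path(out_dir, "per_tissue_elevated.tsv"))
  invisible(list(classes = classes, summary = smry))
}

# Short rule descriptions used in the summary report.
category_definitions <- function() {
  c(tissue_enriched =
      "level in one tissue at least fold x every other tissue",
    group_enriched =
      "mean level in a tissue group at least fold x every tissue outside it",
    enhanced =
      "level in a tissue at least fold x the all-tissue average",
    expressed_in_all = "above the detection cutoff in every tissue",
    mixed = "detected in some tissues without meeting any fold rule",
    not_detected = "below the detection cutoff in every tissue")
}

#' Compare two classification files
#'
#' Reads two classification TSVs (and optionally a tissue mapping), runs
#' [compare_classifications()] and writes `crosstab.tsv`,
#' `per_tissue_agreement.tsv` and `expressed_in_all_overlap.tsv`.
#'
#' @param class_a_path,class_b_path Classification TSVs from
#'   [run_classify()].
#' @param out_dir Output directory.
#' @param mapping_path Optional tissue mapping TSV; default identity mapping
#'   over the tissues seen in either file.
#' @param mode Agreement rule, see [elevated_tissue_agreement()].
#' @return Invisibly, the `concordance_result`.
#' @export
run_compare <- function(class_a_path, class_b_path, out_dir,
                        mapping_path = NULL,
                        mode = c("elevated", "enriched")) {
  mode <- match.arg(mode)
  a <- read_classification(class_a_path)
  b <- read_classification(class_b_path)
  mapping <- if (!is.null(mapping_path)) read_tissue_mapping(mapping_path)
  res <- compare_classifications(a, b, mapping, mode)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ct <- as.data.frame(res$crosstab)
  ct <- cbind(data.frame(category_a = rownames(res$crosstab),
                         stringsAsFactors = FALSE), ct)
  write_table(ct, file.path(out_dir, "crosstab.tsv"))
  write_table(res$per_tissue, file.path(out_dir, "per_tissue_agreement.tsv"))
  e <- res$expressed_in_all
  overlap <- data.frame(
    set = c("both", "only_a", "only_b"),
    count = c(e$both, e$only_a, e$only_b),
    stringsAsFactors = FALSE
  )
  write_table(overlap, file.path(out_dir, "expressed_in_all_overlap.tsv"))
  invisible(res)
}

#' Interindividual CV comparison from files
#'
#' Reads a replicate-level matrix, manifest and classification, and writes
#' per-gene CV records (`cv_records.tsv`) plus one Mann-Whitney comparison
#' row per eligible tissue (`cv_comparison.tsv`).
#'
#' @inheritParams run_classify
#' @param classification_path Classification TSV.
#' @param min_replicates Minimum replicates for a tissue to be analysed.
#' @return Invisibly, the comparison data.frame.
#' @export
run_cv <- function(matrix_path, manifest_path, classification_path, out_dir,
                   params = classifier_params(), min_replicates = 3L) {
  m <- read_expression_matrix(matrix_path)
  manifest <- read_sample_manifest(manifest_path)
  classes <- read_classification(classification_path)
  counts <- table(manifest$tissue[manifest$sample_id %in% colnames(m)])
  tissues <- sort(names(counts)[counts >= min_replicates])
  if (length(tissues) == 0L) {
    stop(sprintf("no tissue has >= %d replicates", min_replicates),
         call. = FALSE)
  }
  records <- do.call(rbind, lapply(tissues, function(t) {
    gene_cv(m, manifest, t, params, min_replicates)
  }))
  comparison <- do.call(rbind, lapply(tissues, function(t) {
    cv_shift_test(classes, records[records$tissue == t, , drop = FALSE])
  }))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_table(records, file.path(out_dir, "cv_records.tsv"))
  write_table(comparison, file.path(out_dir, "cv_comparison.tsv"))
  invisible(comparison)
}

#' Simulate an atlas to files
#'
#' Generates a synthetic atlas and writes `matrix.tsv` (full-precision
#' replicate-level FPKM), `manifest.tsv` and `truth.tsv` to `out_dir`.
#'
#' @param out_dir Output directory.
#' @param spec A [synthetic_spec()].
#' @return Invisibly, the atlas list from [generate_atlas()].
#' @export
run_simulate <- function(out_dir, spec = synthetic_spec()) {
  atlas <- generate_atlas(spec)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_matrix(atlas$matrix, file.path(out_dir, "matrix.tsv"))
  write_table(atlas$manifest, file.path(out_dir, "manifest.tsv"))
  write_table(atlas$truth, file.path(out_dir, "truth.tsv"))
  invisible(atlas)
}
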