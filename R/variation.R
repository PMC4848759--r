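#' Per-gene coefficient of variation across a tissue's replicates
#'
#' For one tissue with several biological replicates, computes each gene's
#' mean, sample (n-1) standard deviation and coefficient of variation
#' (CV = sd / mean) over the replicate FPKM values. Genes whose replicate
#' mean is below the detection cutoff are excluded: the CV ratio is unstable
#' near zero and such genes are not meaningfully expressed in the tissue.
#'
#' @param m Numeric gene x sample matrix (replicate level).
#' @param manifest Sample manifest (`sample_id`, `tissue`).
#' @param tissue Tissue label to analyse.
#' @param params [classifier_params()]; only `cutoff` is used here.
#' @param min_replicates Minimum number of replicate samples required
#'   (default 3).
#' @return Data.frame with columns `gene_id`, `tissue`, `mean`, `sd`, `cv`,
#'   `n_samples`, one row per retained gene, in matrix gene order.
#' @export
gene_cv <- function(m, manifest, tissue, params = classifier_params(),
                    min_replicates = 3L) {
  stopifnot(is.matrix(m), is.numeric(m), !is.null(colnames(m)))
  validate_manifest(manifest)
  if (!tissue %in% manifest$tissue) {
    stop(sprintf("tissue not in manifest: %s", tissue), call. = FALSE)
  }
  cols <- intersect(manifest$sample_id[manifest$tissue == tissue], colnames(m))
  if (length(cols) < min_replicates) {
    stop(sprintf("tissue '%s' has %d replicate(s); need >= %d",
                 tissue, length(cols), min_replicates), call. = FALSE)
  }
  x <- m[, cols, drop = FALSE]
  mu <- rowMeans(x)
  sdv <- apply(x, 1L, stats::sd)
  keep <- mu >= params$cutoff & mu > 0
  data.frame(gene_id = rownames(m)[keep],
             tissue = tissue,
             mean = mu[keep],
             sd = sdv[keep],
             cv = sdv[keep] / mu[keep],
             n_samples = length(cols),
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Test whether ubiquitously expressed genes vary less between individuals
#'
#' Splits a tissue's per-gene CV records into genes classified as
#' "expressed in all tissues" versus all other categories and compares the
#' two CV distributions with a two-sided Mann-Whitney U test (normal
#' approximation with tie correction). The direction indicator reports
#' whether the median CV of the expressed-in-all group is strictly lower —
#' the interindividual-stability signature of housekeeping-like genes.
#'
#' @param classes Classification data.frame (atlas-wide categories).
#' @param cvs CV records from [gene_cv()] for a single tissue.
#' @return One-row data.frame: `tissue`, `n_expressed_in_all`, `n_other`,
#'   `statistic` (Mann-Whitney U for the expressed-in-all group), `p_value`,
#'   `median_cv_expressed_in_all`, `median_cv_other`,
#'   `lower_in_expressed_in_all` (logical).
#' @export
cv_shift_test <- function(classes, cvs) {
  validate_classification(classes)
  stopifnot(is.data.frame(cvs),
            all(c("gene_id", "tissue", "cv") %in% colnames(cvs)))
  tissue <- unique(cvs$tissue)
  if (length(tissue) != 1L) {
    stop("CV records must come from a single tissue", call. = FALSE)
  }
  cat <- classes$category[match(cvs$gene_id, classes$gene_id)]
  if (anyNA(cat)) {
    stop("CV records contain genes absent from the classification",
         call. = FALSE)
  }
  in_all <- cat == "expressed_in_all"
  x <- cvs$cv[in_all]
  y <- cvs$cv[!in_all]
  if (length(x) < 2L || length(y) < 2L) {
    stop("each group needs at least 2 genes for the rank test", call. = FALSE)
  }
  wt <- stats::wilcox.test(x, y, alternative = "two.sided",
                           exact = FALSE, correct = TRUE)
  med_x <- stats::median(x)
  med_y <- stats::median(y)
  data.frame(tissue = tissue,
             n_expressed_in_all = length(x),
             n_other = length(y),
             statistic = unname(wt$statistic),
             p_value = wt$p.value,
             median_cv_expressed_in_all = med_x,
             median_cv_other = med_y,
             lower_in_expressed_in_all = med_x < med_y,
             stringsAsFactors = FALSE)
}

#' CV comparison across all eligible tissues
#'
#' Runs [gene_cv()] and [cv_shift_test()] for every tissue with at least
#' `min_replicates` replicate samples.
#'
#' @inheritParams gene_cv
#' @param classes Classification data.frame.
#' @param tissues Tissues to analyse; default all tissues meeting
#'   `min_replicates`.
#' @return Data.frame with one [cv_shift_test()] row per tissue.
#' @export
cv_compare_tissues <- function(m, manifest, classes,
                               params = classifier_params(),
                               min_replicates = 3L, tissues = NULL) {
  validate_manifest(manifest)
  counts <- table(manifest$tissue[manifest$sample_id %in% colnames(m)])
  eligible <- sort(names(counts)[counts >= min_replicates])
  if (is.null(tissues)) tissues <- eligible
  if (length(tissues) == 0L) {
    stop(sprintf("no tissue has >= %d replicates", min_replicates),
         call. = FALSE)
  }
  rows <- lapply(tissues, function(t) {
    cv_shift_test(classes, gene_cv(m, manifest, t, params, min_replicates))
  })
  do.call(rbind, rows)
}
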