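#' Classify one gene's per-tissue expression profile
#'
#' Assigns a single expression vector to exactly one of the six specificity
#' categories. Rules are evaluated in precedence order, first match wins:
#'
#' 1. **not_detected** — every tissue below the detection cutoff.
#' 2. **tissue_enriched** — one tissue detected and at least `fold` times the
#'    highest level among all other tissues.
#' 3. **group_enriched** — for some group size k in `group_min..group_max`,
#'    the k highest tissues are all detected and their mean is at least
#'    `fold` times the highest remaining tissue; the smallest such k is
#'    reported. Searching only the top-k tissues is equivalent to exhaustive
#'    search over all size-k tissue subsets, because the top-k maximise the
#'    group mean and minimise the best excluded tissue simultaneously.
#' 4. **enhanced** — some detected tissue is at least `fold` times the mean
#'    level over all tissues (the candidate included); all such tissues are
#'    reported as elevated.
#' 5. **expressed_in_all** — detected in every tissue.
#' 6. **mixed** — everything else.
#'
#' All comparisons are inclusive (`>=`, "at least fold-fold") and
#' multiplicative (`x >= fold * reference`), so a reference of zero is legal.
#' The reported `fold_score` divides by the reference guarded from below at
#' `cutoff / fold`; it is 0 for the non-elevated categories.
#'
#' @param values Named non-negative numeric vector of per-tissue FPKM values
#'   (>= 2 tissues). Unnamed vectors get labels `T1, T2, ...`.
#' @param params A [classifier_params()] object.
#' @return A list with elements `category`, `elevated_tissues` (character,
#'   lexicographically sorted, empty unless elevated), `fold_score` and
#'   `n_detected`.
#' @export
#' @examples
#' p <- classifier_params()
#' classify_gene(c(A = 10, B = 1, C = 1, D = 1, E = 1, F = 1), p)$category
#' classify_gene(c(A = 10, B = 9, C = 1, D = 1, E = 1, F = 1), p)
classify_gene <- function(values, params = classifier_params()) {
  n <- length(values)
  if (n < 2L) {
    stop("classification needs at least 2 tissues", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("expression values must be finite and non-missing", call. = FALSE)
  }
  if (any(values < 0)) {
    stop("expression values must be non-negative", call. = FALSE)
  }
  labels <- names(values)
  if (is.null(labels)) labels <- paste0("T", seq_len(n))

  cutoff <- params$cutoff
  fold <- params$fold
  n_detected <- sum(values >= cutoff)

  res <- function(category, elevated = character(0), fold_score = 0) {
    list(category = category,
         elevated_tissues = sort(elevated),
         fold_score = unname(fold_score),
         n_detected = as.integer(n_detected))
  }
  guarded_ratio <- function(num, den) {
    den <- max(cutoff / fold, den)
    if (den > 0) num / den else 0
  }

  ## (1) nothing above the detection threshold
  if (all(values < cutoff)) return(res("not_detected"))

  ## descending by value, ties broken lexicographically by tissue label
  ord <- order(-values, labels)
  v <- values[ord]
  lab <- labels[ord]

  ## (2) single-tissue enrichment: only the top tissue can qualify
  if (v[1L] >= cutoff && v[1L] >= fold * v[2L]) {
    return(res("tissue_enriched", lab[1L], guarded_ratio(v[1L], v[2L])))
  }

  ## (3) group enrichment over the top-k tissues, smallest k first
  kmax <- min(params$group_max, n - 1L)
  if (params$group_min <= kmax) {
    cm <- cumsum(v)
    for (k in params$group_min:kmax) {
      if (v[k] < cutoff) break  # sorted: larger groups cannot all be detected
      if (cm[k] / k >= fold * v[k + 1L]) {
        return(res("group_enriched", lab[seq_len(k)],
                   guarded_ratio(cm[k] / k, v[k + 1L])))
      }
    }
  }

  ## (4) enhanced over the all-tissue mean (candidate included)
  mu <- mean(values)
  hit <- values >= cutoff & values >= fold * mu
  if (any(hit)) {
    return(res("enhanced", labels[hit], guarded_ratio(max(values[hit]), mu)))
  }

  ## (5)/(6) detected everywhere vs. partial detection
  if (all(values >= cutoff)) return(res("expressed_in_all"))
  res("mixed")
}

#' Classify every gene of an expression matrix
#'
#' Applies [classify_gene()] to each row of a gene x tissue matrix. The
#' result is a pure function of the matrix and parameters; permuting tissue
#' columns does not change any category or elevated tissue set.
#'
#' @param m Numeric gene x tissue matrix with dimnames (e.g. from
#'   [aggregate_to_tissue()]).
#' @param params A [classifier_params()] object.
#' @return A data.frame with one row per gene, in input order: `gene_id`,
#'   `category`, `elevated_tissues` (semicolon-joined, empty string when
#'   none), `fold_score`, `n_detected`.
#' @export
classify_matrix <- function(m, params = classifier_params()) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("matrix must have gene rownames and tissue colnames", call. = FALSE)
  }
  if (ncol(m) < 2L) {
    stop("classification needs at least 2 tissues", call. = FALSE)
  }
  if (anyDuplicated(colnames(m))) {
    stop("tissue labels must be unique", call. = FALSE)
  }
  n <- nrow(m)
  category <- character(n)
  elevated <- character(n)
  fold_score <- numeric(n)
  n_detected <- integer(n)
  for (i in seq_len(n)) {
    cl <- classify_gene(m[i, ], params)
    category[i] <- cl$category
    elevated[i] <- paste(cl$elevated_tissues, collapse = ";")
    fold_score[i] <- cl$fold_score
    n_detected[i] <- cl$n_detected
  }
  data.frame(gene_id = rownames(m), category = category,
             elevated_tissues = elevated, fold_score = fold_score,
             n_detected = n_detected, stringsAsFactors = FALSE)
}

split_tissues <- function(x) {
  lapply(strsplit(x, ";", fixed = TRUE), function(v) v[nzchar(v)])
}

validate_classification <- function(classes) {
  need <- c("gene_id", "category", "elevated_tissues", "fold_score",
            "n_detected")
  if (!is.data.frame(classes) || !all(need %in% colnames(classes))) {
    stop("not a classification table (expected columns: ",
         paste(need, collapse = ", "), ")", call. = FALSE)
  }
  bad <- setdiff(unique(classes$category), expression_categories())
  if (length(bad)) {
    stop(sprintf("unknown category label: %s", bad[1L]), call. = FALSE)
  }
  invisible(classes)
}

#' Summarize a classification
#'
#' Tallies a gene classification into per-category counts and integer
#' percentages, the total elevated count (tissue enriched + group enriched +
#' enhanced), and per-tissue elevated-gene counts where a gene contributes to
#' every tissue in its elevated set.
#'
#' @param classes Classification data.frame from [classify_matrix()].
#' @return An object of class `classification_summary`: a list with
#'   `categories` (data.frame `category`, `count`, `percent`), `total`,
#'   `total_elevated`, and `per_tissue` (data.frame `tissue` plus one column
#'   per elevated category and `total_elevated`).
#' @export
summarize_classification <- function(classes) {
  validate_classification(classes)
  if (nrow(classes) == 0L) stop("empty classification", call. = FALSE)
  counts <- table(factor(classes$category, levels = expression_categories()))
  smry <- summarize_counts(as.numeric(counts))

  elev <- classes[classes$category %in% elevated_categories(), , drop = FALSE]
  tiss_sets <- split_tissues(elev$elevated_tissues)
  tissues <- sort(unique(unlist(tiss_sets)))
  per_tissue <- data.frame(tissue = tissues, stringsAsFactors = FALSE)
  for (cat in elevated_categories()) {
    in_cat <- unlist(tiss_sets[elev$category == cat])
    tab <- table(factor(in_cat, levels = tissues))
    per_tissue[[cat]] <- as.integer(tab)
  }
  per_tissue$total_elevated <- per_tissue$tissue_enriched +
    per_tissue$group_enriched + per_tissue$enhanced
  smry$per_tissue <- per_tissue
  smry
}

#' Summarize printed per-category counts
#'
#' Builds a [summarize_classification()]-style summary directly from six
#' per-category gene counts — useful for checking published atlas tallies
#' without the underlying matrix.
#'
#' @param counts Numeric vector of six non-negative counts. If named, names
#'   must be the category labels of [expression_categories()] (any order);
#'   unnamed vectors are taken in that canonical order.
#' @return An object of class `classification_summary` (without the
#'   `per_tissue` table).
#' @export
#' @examples
#' s <- summarize_counts(c(2359, 1208, 3227, 8385, 2484, 1021))
#' s$total          # 18684
#' s$total_elevated # 6794
summarize_counts <- function(counts) {
  stopifnot(is.numeric(counts), length(counts) == 6L, all(counts >= 0))
  cats <- expression_categories()
  if (!is.null(names(counts))) {
    if (!setequal(names(counts), cats)) {
      stop("count names must be the six category labels", call. = FALSE)
    }
    counts <- counts[cats]
  }
  counts <- as.numeric(counts)
  total <- sum(counts)
  if (total <= 0) stop("counts sum to zero", call. = FALSE)
  structure(
    list(
      categories = data.frame(
        category = cats,
        count = counts,
        percent = as.integer(round(100 * counts / total)),
        stringsAsFactors = FALSE
      ),
      total = total,
      total_elevated = sum(counts[match(elevated_categories(), cats)]),
      per_tissue = NULL
    ),
    class = "classification_summary"
  )
}

#' @export
print.classification_summary <- function(x, ...) {
  cat(sprintf("Classification of %d genes\n", x$total))
  df <- x$categories
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-17s %6d  (%d%%)\n", df$category[i], df$count[i],
                df$percent[i]))
  }
  cat(sprintf("  %-17s %6d\n", "total elevated", x$total_elevated))
  if (!is.null(x$per_tissue)) {
    cat(sprintf("  elevated genes span %d tissues\n", nrow(x$per_tissue)))
  }
  invisible(x)
}

#' Write a classification table to TSV
#'
#' Columns: `gene_id`, `category`, `elevated_tissues` (semicolon-joined),
#' `fold_score` (4 decimals), `n_detected`.
#'
#' @param classes Classification data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_classification <- function(classes, path) {
  validate_classification(classes)
  write_table(classes, path)
}

#' Read a classification table from TSV
#'
#' @param path Path written by [write_classification()].
#' @return Classification data.frame.
#' @export
read_classification <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("classification file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = c(gene_id = "character",
                                         category = "character",
                                         elevated_tissues = "character",
                                         fold_score = "numeric",
                                         n_detected = "integer"))
  df$elevated_tissues[is.na(df$elevated_tissues)] <- ""
  bad <- which(!df$category %in% expression_categories())
  if (length(bad)) {
    stop(sprintf("line %d: unknown category '%s'", bad[1L] + 1L,
                 df$category[bad[1L]]), call. = FALSE)
  }
  validate_classification(df)
}
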