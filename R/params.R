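#' Expression-specificity categories
#'
#' The six mutually exclusive categories a gene can be assigned to, in
#' classification precedence order. The first three are the "elevated"
#' categories.
#'
#' @return Character vector of the six category labels.
#' @export
#' @examples
#' expression_categories()
expression_categories <- function() {
  c("tissue_enriched", "group_enriched", "enhanced",
    "expressed_in_all", "mixed", "not_detected")
}

#' Elevated categories
#'
#' @return Character vector of the three elevated category labels
#'   (tissue enriched, group enriched, tissue enhanced).
#' @export
elevated_categories <- function() {
  c("tissue_enriched", "group_enriched", "enhanced")
}

#' Classifier parameters
#'
#' Bundles the tunable constants of the specificity classifier.
#'
#' @param cutoff Detection threshold in FPKM; a gene counts as detected in a
#'   tissue when its level is at least `cutoff`. Default 0.5.
#' @param fold Enrichment fold factor; elevated calls require a tissue (or
#'   group mean) at least `fold` times its reference. Default 5.
#' @param group_min,group_max Smallest and largest group size considered for
#'   the group-enriched rule. Defaults 2 and 7. When a matrix has fewer than
#'   `group_max + 1` tissues the effective upper bound is capped at
#'   `n_tissues - 1` (a group must leave at least one tissue outside).
#'
#' @return An object of class `classifier_params`.
#' @export
#' @examples
#' classifier_params()
#' classifier_params(cutoff = 1, fold = 4)
classifier_params <- function(cutoff = 0.5, fold = 5, group_min = 2L,
                              group_max = 7L) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L, is.finite(cutoff),
            is.numeric(fold), length(fold) == 1L, is.finite(fold))
  if (cutoff < 0) stop("`cutoff` must be >= 0", call. = FALSE)
  if (fold <= 1) stop("`fold` must be > 1", call. = FALSE)
  group_min <- as.integer(group_min)
  group_max <- as.integer(group_max)
  if (group_min < 2L) stop("`group_min` must be >= 2", call. = FALSE)
  if (group_max < group_min) {
    stop("`group_max` must be >= `group_min`", call. = FALSE)
  }
  structure(
    list(cutoff = cutoff, fold = fold,
         group_min = group_min, group_max = group_max),
    class = "classifier_params"
  )
}

#' @export
print.classifier_params <- function(x, ...) {
  cat("Classifier parameters\n")
  cat(sprintf("  detection cutoff : %g FPKM\n", x$cutoff))
  cat(sprintf("  enrichment fold  : %g\n", x$fold))
  cat(sprintf("  group size       : %d..%d tissues\n",
              x$group_min, x$group_max))
  invisible(x)
}
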