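#' Genes shared between two classifications
#'
#' @param a,b Classification data.frames (see [classify_matrix()]).
#' @return Character vector of gene ids present in both, sorted
#'   lexicographically.
#' @export
intersect_genes <- function(a, b) {
  validate_classification(a)
  validate_classification(b)
  if (anyDuplicated(a$gene_id)) {
    stop("duplicate gene id in first classification", call. = FALSE)
  }
  if (anyDuplicated(b$gene_id)) {
    stop("duplicate gene id in second classification", call. = FALSE)
  }
  sort(intersect(a$gene_id, b$gene_id))
}

#' Cross-tabulate categories between two classifications
#'
#' @param a,b Classification data.frames.
#' @param shared Gene ids to tabulate; defaults to [intersect_genes()].
#' @return A list with `crosstab` (6x6 integer matrix, rows = categories in
#'   `a`, columns = categories in `b`), `margin_a`, `margin_b` (named count
#'   vectors) and `shared_gene_count`.
#' @export
category_crosstab <- function(a, b, shared = intersect_genes(a, b)) {
  validate_classification(a)
  validate_classification(b)
  if (!all(shared %in% a$gene_id) || !all(shared %in% b$gene_id)) {
    stop("`shared` must be a subset of both gene id sets", call. = FALSE)
  }
  cats <- expression_categories()
  ca <- factor(a$category[match(shared, a$gene_id)], levels = cats)
  cb <- factor(b$category[match(shared, b$gene_id)], levels = cats)
  tab <- table(ca, cb, dnn = c("a", "b"))
  m <- matrix(as.integer(tab), nrow = 6L, dimnames = list(cats, cats))
  list(crosstab = m,
       margin_a = rowSums(m),
       margin_b = colSums(m),
       shared_gene_count = length(shared))
}

#' Overlap of "expressed in all tissues" calls between two atlases
#'
#' Counts the genes called ubiquitously expressed by both datasets, by only
#' one, and — for each one-sided set — how the other dataset classified those
#' genes (the category breakdown behind the discordance: typically most land
#' in "mixed", i.e. they dip under the detection cutoff in at least one
#' tissue of the other atlas).
#'
#' @param a,b Classification data.frames.
#' @param shared Gene ids considered; defaults to [intersect_genes()].
#' @return A list with counts `both`, `only_a`, `only_b` and named count
#'   vectors `only_a_by_b_category`, `only_b_by_a_category`.
#' @export
expressed_in_all_overlap <- function(a, b, shared = intersect_genes(a, b)) {
  validate_classification(a)
  validate_classification(b)
  ca <- a$category[match(shared, a$gene_id)]
  cb <- b$category[match(shared, b$gene_id)]
  in_a <- ca == "expressed_in_all"
  in_b <- cb == "expressed_in_all"
  cats <- expression_categories()
  list(
    both = sum(in_a & in_b),
    only_a = sum(in_a & !in_b),
    only_b = sum(!in_a & in_b),
    only_a_by_b_category =
      as.integer(table(factor(cb[in_a & !in_b], levels = cats))) |>
        stats::setNames(cats),
    only_b_by_a_category =
      as.integer(table(factor(ca[!in_a & in_b], levels = cats))) |>
        stats::setNames(cats)
  )
}

#' Read a tissue-name mapping table from TSV
#'
#' Expected columns `tissue_a` and `tissue_b`, one pair per row;
#' many-to-many mappings are allowed (e.g. one dataset's single "brain"
#' tissue against another's cerebellum/cortex/pituitary samples).
#'
#' @param path Path to a TSV file.
#' @return Data.frame with character columns `tissue_a`, `tissue_b`.
#' @export
read_tissue_mapping <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("tissue mapping file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  if (!all(c("tissue_a", "tissue_b") %in% colnames(df))) {
    stop("mapping must have columns 'tissue_a' and 'tissue_b'", call. = FALSE)
  }
  df[, c("tissue_a", "tissue_b")]
}

#' Identity tissue mapping
#'
#' Convenience constructor mapping each tissue label to itself, for
#' comparing two atlases that use the same tissue vocabulary.
#'
#' @param tissues Character vector of tissue labels.
#' @return Mapping data.frame with columns `tissue_a`, `tissue_b`.
#' @export
identity_mapping <- function(tissues) {
  data.frame(tissue_a = tissues, tissue_b = tissues, stringsAsFactors = FALSE)
}

#' Per-tissue agreement of elevated gene calls between two atlases
#'
#' For every gene that is tissue enriched in either dataset, decides whether
#' the other dataset supports the call in the corresponding tissue(s). A gene
#' tissue-enriched in dataset A at tissue `t` counts as `both` for `t`'s
#' tissue group when dataset B places it in an elevated category
#' (`mode = "elevated"`, the default) — or is itself tissue enriched
#' (`mode = "enriched"`) — in at least one tissue mapped to `t`; otherwise it
#' counts as `only_a`. Symmetrically for genes tissue-enriched in B, with
#' results attributed to each mapped A-side tissue label. Genes enriched in a
#' tissue with no mapping partner are tallied under the reserved label
#' `"unmapped"` and reported with a warning.
#'
#' @param a,b Classification data.frames.
#' @param mapping Mapping data.frame (`tissue_a`, `tissue_b`); see
#'   [read_tissue_mapping()] and [identity_mapping()].
#' @param shared Gene ids considered; defaults to [intersect_genes()].
#' @param mode `"elevated"` (agreement = any elevated category in a partner
#'   tissue) or `"enriched"` (strict tissue-enriched/tissue-enriched match).
#' @param tissues_a,tissues_b Optional full tissue vocabularies used to
#'   validate the mapping; defaults skip the existence check.
#' @return Data.frame with columns `tissue` (A-side label, plus possibly
#'   `"unmapped"`), `both`, `only_a`, `only_b`, sorted by tissue.
#' @export
elevated_tissue_agreement <- function(a, b, mapping,
                                      shared = intersect_genes(a, b),
                                      mode = c("elevated", "enriched"),
                                      tissues_a = NULL, tissues_b = NULL) {
  validate_classification(a)
  validate_classification(b)
  mode <- match.arg(mode)
  stopifnot(is.data.frame(mapping),
            all(c("tissue_a", "tissue_b") %in% colnames(mapping)))
  if (!is.null(tissues_a) && !all(mapping$tissue_a %in% tissues_a)) {
    stop("mapping refers to unknown tissue in dataset A", call. = FALSE)
  }
  if (!is.null(tissues_b) && !all(mapping$tissue_b %in% tissues_b)) {
    stop("mapping refers to unknown tissue in dataset B", call. = FALSE)
  }
  a2b <- split(mapping$tissue_b, mapping$tissue_a)
  b2a <- split(mapping$tissue_a, mapping$tissue_b)

  ia <- match(shared, a$gene_id)
  ib <- match(shared, b$gene_id)
  cat_a <- a$category[ia]
  cat_b <- b$category[ib]
  elev_a <- split_tissues(a$elevated_tissues[ia])
  elev_b <- split_tissues(b$elevated_tissues[ib])
  match_cats <- if (mode == "elevated") elevated_categories() else
    "tissue_enriched"

  sets <- list()  # per group label: both / only_a / only_b gene-id sets
  add <- function(group, slot, gene) {
    if (is.null(sets[[group]])) {
      sets[[group]] <<- list(both = character(0), only_a = character(0),
                             only_b = character(0))
    }
    sets[[group]][[slot]] <<- c(sets[[group]][[slot]], gene)
  }
  n_unmapped <- 0L

  for (i in seq_along(shared)) {
    g <- shared[i]
    if (cat_a[i] == "tissue_enriched") {
      t <- elev_a[[i]][1L]
      partners <- a2b[[t]]
      if (is.null(partners)) {
        add("unmapped", "only_a", g)
        n_unmapped <- n_unmapped + 1L
      } else {
        hit <- cat_b[i] %in% match_cats &&
          length(intersect(elev_b[[i]], partners)) > 0L
        add(t, if (hit) "both" else "only_a", g)
      }
    }
    if (cat_b[i] == "tissue_enriched") {
      u <- elev_b[[i]][1L]
      groups <- b2a[[u]]
      if (is.null(groups)) {
        add("unmapped", "only_b", g)
        n_unmapped <- n_unmapped + 1L
      } else {
        for (t in groups) {
          partners <- a2b[[t]]
          hit <- cat_a[i] %in% match_cats &&
            length(intersect(elev_a[[i]], partners)) > 0L
          add(t, if (hit) "both" else "only_b", g)
        }
      }
    }
  }
  if (n_unmapped > 0L) {
    warning(sprintf("%d enriched gene call(s) in unmapped tissues", n_unmapped),
            call. = FALSE)
  }

  groups <- sort(names(sets))
  out <- data.frame(tissue = groups, both = 0L, only_a = 0L, only_b = 0L,
                    stringsAsFactors = FALSE)
  for (r in seq_along(groups)) {
    s <- sets[[groups[r]]]
    both <- unique(s$both)
    out$both[r] <- length(both)
    out$only_a[r] <- length(setdiff(unique(s$only_a), both))
    out$only_b[r] <- length(setdiff(unique(s$only_b), both))
  }
  out
}

#' Full concordance analysis of two classifications
#'
#' Convenience wrapper bundling [category_crosstab()],
#' [expressed_in_all_overlap()] and [elevated_tissue_agreement()] on the
#' shared gene universe.
#'
#' @inheritParams elevated_tissue_agreement
#' @return A list of class `concordance_result` with elements
#'   `shared_gene_count`, `crosstab`, `expressed_in_all`, `per_tissue`.
#' @export
compare_classifications <- function(a, b, mapping = NULL,
                                    mode = c("elevated", "enriched")) {
  mode <- match.arg(mode)
  shared <- intersect_genes(a, b)
  if (length(shared) == 0L) {
    warning("no shared genes between the two classifications", call. = FALSE)
  }
  if (is.null(mapping)) {
    tissues <- sort(unique(unlist(split_tissues(
      c(a$elevated_tissues, b$elevated_tissues)))))
    mapping <- identity_mapping(tissues)
  }
  ct <- category_crosstab(a, b, shared)
  structure(
    list(shared_gene_count = length(shared),
         crosstab = ct$crosstab,
         margin_a = ct$margin_a,
         margin_b = ct$margin_b,
         expressed_in_all = expressed_in_all_overlap(a, b, shared),
         per_tissue = if (length(shared)) {
           elevated_tissue_agreement(a, b, mapping, shared, mode)
         } else {
           data.frame(tissue = character(0), both = integer(0),
                      only_a = integer(0), only_b = integer(0))
         }),
    class = "concordance_result"
  )
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("Concordance over %d shared genes\n", x$shared_gene_count))
  cat(sprintf("  same category in both: %d (%.1f%%)\n",
              sum(diag(x$crosstab)),
              if (x$shared_gene_count > 0)
                100 * sum(diag(x$crosstab)) / x$shared_gene_count else 0))
  e <- x$expressed_in_all
  cat(sprintf("  expressed in all: both %d, only A %d, only B %d\n",
              e$both, e$only_a, e$only_b))
  cat(sprintf("  per-tissue agreement rows: %d\n", nrow(x$per_tissue)))
  invisible(x)
}
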