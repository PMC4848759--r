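# Independent straight-line re-implementation of the six-category rules,
# used as the reference the fast classifier is checked against. The group
# rule is evaluated by exhaustive enumeration over all tissue subsets of
# sizes group_min..group_max (not just the top-k), so agreement between the
# two is evidence that the top-k search is equivalent to brute force.

oracle_group_search <- function(values, cutoff, fold, group_min, group_max) {
  n <- length(values)
  for (k in seq(group_min, min(group_max, n - 1L))) {
    subsets <- utils::combn(n, k)
    hits <- list()
    for (j in seq_len(ncol(subsets))) {
      idx <- subsets[, j]
      if (all(values[idx] >= cutoff) &&
          mean(values[idx]) >= fold * max(values[-idx])) {
        hits[[length(hits) + 1L]] <- idx
      }
    }
    if (length(hits)) return(list(k = k, subsets = hits))
  }
  NULL
}

classify_gene_oracle <- function(values, cutoff = 0.5, fold = 5,
                                 group_min = 2L, group_max = 7L) {
  n <- length(values)
  labels <- names(values)
  if (is.null(labels)) labels <- paste0("T", seq_len(n))
  if (all(values < cutoff)) {
    return(list(category = "not_detected", elevated = character(0)))
  }
  for (t in seq_len(n)) {
    if (values[t] >= cutoff && values[t] >= fold * max(values[-t])) {
      return(list(category = "tissue_enriched", elevated = labels[t]))
    }
  }
  grp <- oracle_group_search(values, cutoff, fold, group_min, group_max)
  if (!is.null(grp)) {
    return(list(category = "group_enriched", k = grp$k,
                candidate_sets = lapply(grp$subsets,
                                        function(i) sort(labels[i]))))
  }
  mu <- mean(values)
  hit <- which(values >= cutoff & values >= fold * mu)
  if (length(hit)) {
    return(list(category = "enhanced", elevated = sort(labels[hit])))
  }
  if (all(values >= cutoff)) {
    return(list(category = "expressed_in_all", elevated = character(0)))
  }
  list(category = "mixed", elevated = character(0))
}

# Random expression vectors stressing boundaries: zeros, sub-cutoff values,
# log-normal levels, and ties induced by coarse rounding.
random_gene_vector <- function(n) {
  v <- stats::rlnorm(n, meanlog = 0, sdlog = 2)
  z <- stats::runif(n)
  v[z < 0.2] <- 0
  v[z >= 0.2 & z < 0.4] <- stats::runif(sum(z >= 0.2 & z < 0.4), 0, 0.5)
  if (stats::runif(1) < 0.5) v <- round(v, 1)
  names(v) <- sprintf("t%02d", seq_len(n))
  v
}

# Minimal classification table for concordance tests.
make_classes <- function(gene_id, category, elevated = "") {
  data.frame(gene_id = gene_id, category = category,
             elevated_tissues = elevated,
             fold_score = 0, n_detected = 1L,
             stringsAsFactors = FALSE)
}
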