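p_default <- classifier_params()

test_that("single-gene rules assign the documented categories", {
  expect_equal(classify_gene(rep(0, 6) |> setNames(LETTERS[1:6]), p_default),
               list(category = "not_detected", elevated_tissues = character(0),
                    fold_score = 0, n_detected = 0L))

  all10 <- classify_gene(setNames(rep(10, 6), LETTERS[1:6]), p_default)
  expect_identical(all10$category, "expressed_in_all")
  expect_identical(all10$n_detected, 6L)

  enr <- classify_gene(c(A = 10, B = 1, C = 1, D = 1, E = 1, F = 1), p_default)
  expect_identical(enr$category, "tissue_enriched")
  expect_identical(enr$elevated_tissues, "A")
  expect_equal(enr$fold_score, 10)

  # inclusive "at least fivefold": exactly 5x the runner-up still qualifies
  edge <- classify_gene(c(A = 5, B = 1, C = 0.1, D = 0.1), p_default)
  expect_identical(edge$category, "tissue_enriched")
  expect_identical(edge$elevated_tissues, "A")

  grp <- classify_gene(c(A = 10, B = 9, C = 1, D = 1, E = 1, F = 1), p_default)
  expect_identical(grp$category, "group_enriched")
  expect_identical(grp$elevated_tissues, c("A", "B"))
  expect_equal(grp$fold_score, 9.5)

  # 32 tissues: 1 high, 7 moderate, 24 at the cutoff -> enhanced only
  v <- setNames(c(10, rep(4, 7), rep(0.5, 24)), sprintf("t%02d", 1:32))
  enh <- classify_gene(v, p_default)
  expect_identical(enh$category, "enhanced")
  expect_identical(enh$elevated_tissues, "t01")
  expect_equal(enh$fold_score, 10 / mean(v))
  expect_identical(enh$n_detected, 32L)

  mix <- classify_gene(c(A = 0.6, B = 0.6, C = 0.2, D = 0.2, E = 0.2, F = 0.2),
                       p_default)
  expect_identical(mix$category, "mixed")
  expect_identical(mix$n_detected, 2L)
})

test_that("worked group and enhanced examples agree with the exhaustive oracle", {
  grp_v <- c(A = 10, B = 9, C = 1, D = 1, E = 1, F = 1)
  o <- classify_gene_oracle(grp_v)
  expect_identical(o$category, "group_enriched")
  expect_identical(o$k, 2L)
  expect_identical(o$candidate_sets, list(c("A", "B")))

  enh_v <- setNames(c(10, rep(4, 7), rep(0.5, 24)), sprintf("t%02d", 1:32))
  o2 <- classify_gene_oracle(enh_v)
  expect_identical(o2$category, "enhanced")
  expect_identical(o2$elevated, "t01")
})

test_that("classify_gene validates its inputs", {
  expect_error(classify_gene(c(A = 1)), "at least 2 tissues")
  expect_error(classify_gene(c(A = 1, B = -0.1)), "non-negative")
  expect_error(classify_gene(c(A = 1, B = NA)), "finite")
})

test_that("a zero reference is legal for the multiplicative enrichment rule", {
  only <- classify_gene(c(A = 3, B = 0, C = 0), p_default)
  expect_identical(only$category, "tissue_enriched")
  # guarded denominator: reference floored at cutoff / fold
  expect_equal(only$fold_score, 3 / (0.5 / 5))
})

test_that("boundary cases are inclusive (>=, never >)", {
  # enhanced at exactly fold x mean: 32 tissues (1 high, 8 moderate at 4,
  # 23 at 0.5); h = 5 * mean(all) solves to 217.5/27, below 5 x 4 so the
  # enriched and group rules cannot fire
  h <- 217.5 / 27
  v <- setNames(c(h, rep(4, 8), rep(0.5, 23)), sprintf("t%02d", 1:32))
  expect_equal(h, 5 * mean(v))
  expect_identical(classify_gene(v, p_default)$category, "enhanced")
  # group mean at exactly fold x best outsider
  g <- c(A = 6, B = 4, C = 1, D = 0.2, E = 0.2, F = 0.2)
  expect_identical(classify_gene(g, p_default)$category, "group_enriched")
  expect_equal(mean(g[1:2]), 5 * g[["C"]])
})

test_that("matrix classification composes rows, is order-invariant and pure", {
  m <- rbind(g_nd = rep(0, 6),
             g_all = rep(10, 6),
             g_enr = c(10, 1, 1, 1, 1, 1))
  colnames(m) <- LETTERS[1:6]
  cl <- classify_matrix(m, p_default)
  expect_identical(cl$gene_id, c("g_nd", "g_all", "g_enr"))
  expect_identical(cl$category,
                   c("not_detected", "expressed_in_all", "tissue_enriched"))

  perm <- c(4, 2, 6, 1, 3, 5)
  cl2 <- classify_matrix(m[, perm], p_default)
  expect_identical(cl2$category, cl$category)
  expect_identical(cl2$elevated_tissues, cl$elevated_tissues)
  expect_identical(classify_matrix(m, p_default), cl)
})

test_that("fast classifier matches the independent oracle on random matrices", {
  set.seed(303)
  n_genes <- 500
  for (i in seq_len(n_genes)) {
    n <- sample(4:10, 1)
    v <- random_gene_vector(n)
    got <- classify_gene(v, p_default)
    want <- classify_gene_oracle(v)
    expect_identical(got$category, want$category,
                     label = paste("categories for", paste(v, collapse = ",")))
    if (want$category == "group_enriched") {
      # top-k group must be a qualifying subset of the smallest size
      expect_identical(length(got$elevated_tissues), as.integer(want$k))
      expect_true(any(vapply(want$candidate_sets, identical, logical(1),
                             y = got$elevated_tissues)))
    } else if (want$category %in% c("tissue_enriched", "enhanced")) {
      expect_identical(got$elevated_tissues, want$elevated)
    }
  }
})

test_that("scale invariance: detected genes keep their category under scaling", {
  set.seed(404)
  for (i in 1:50) {
    v <- stats::rlnorm(8, 1, 1) + 0.5  # min >= cutoff
    names(v) <- LETTERS[1:8]
    base <- classify_gene(v, p_default)$category
    for (c0 in c(1, 3.7, 100)) {
      expect_identical(classify_gene(c0 * v, p_default)$category, base)
    }
  }
})

test_that("elevated calls shrink with fold and not_detected grows with cutoff", {
  set.seed(505)
  atlas <- generate_atlas(synthetic_spec(n_genes = 400, seed = 99))
  em <- aggregate_to_tissue(atlas$matrix, atlas$manifest)
  folds <- c(2, 5, 10, 100)
  elev <- vapply(folds, function(f) {
    summarize_classification(
      classify_matrix(em, classifier_params(fold = f)))$total_elevated
  }, numeric(1))
  expect_true(all(diff(elev) <= 0))

  cutoffs <- c(0.1, 0.5, 1.0)
  nd <- vapply(cutoffs, function(c0) {
    cl <- classify_matrix(em, classifier_params(cutoff = c0))
    sum(cl$category == "not_detected")
  }, numeric(1))
  expect_true(all(diff(nd) >= 0))
})

test_that("summaries reproduce published atlas tallies and percentages", {
  hpa <- summarize_counts(c(2359, 1208, 3227, 8385, 2484, 1021))
  expect_equal(hpa$total, 18684)
  expect_equal(hpa$total_elevated, 6794)
  pct <- setNames(hpa$categories$percent, hpa$categories$category)
  expect_equal(pct[["expressed_in_all"]], 45L)
  expect_equal(pct[["mixed"]], 13L)
  expect_equal(pct[["tissue_enriched"]], 13L)
  expect_equal(pct[["not_detected"]], 5L)

  gtex <- summarize_counts(c(2289, 1307, 3077, 8459, 2537, 1015))
  expect_equal(gtex$total, 18684)
  expect_equal(gtex$total_elevated, 6673)
})

test_that("summarize partitions genes and counts per-tissue elevated calls", {
  cl <- make_classes(
    c("g1", "g2", "g3", "g4"),
    c("tissue_enriched", "group_enriched", "enhanced", "expressed_in_all"),
    c("liver", "liver;lung", "lung", ""))
  s <- summarize_classification(cl)
  expect_equal(s$total, 4)
  expect_equal(sum(s$categories$count), 4)
  expect_equal(s$total_elevated, 3)
  pt <- s$per_tissue
  expect_identical(pt$tissue, c("liver", "lung"))
  expect_equal(pt$tissue_enriched, c(1L, 0L))
  expect_equal(pt$group_enriched, c(1L, 1L))
  expect_equal(pt$enhanced, c(0L, 1L))
  expect_equal(pt$total_elevated, c(2L, 2L))

  single <- summarize_classification(make_classes("g1", "expressed_in_all"))
  expect_equal(single$categories$count[4], 1)
  expect_equal(sum(single$categories$count), 1)
  expect_equal(single$categories$percent[4], 100L)
})

test_that("classification tables survive a TSV round trip", {
  set.seed(606)
  atlas <- generate_atlas(synthetic_spec(n_genes = 60, seed = 5))
  em <- aggregate_to_tissue(atlas$matrix, atlas$manifest)
  cl <- classify_matrix(em)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_classification(cl, path)
  back <- read_classification(path)
  expect_identical(back$gene_id, cl$gene_id)
  expect_identical(back$category, cl$category)
  expect_identical(back$elevated_tissues, cl$elevated_tissues)
  expect_identical(back$n_detected, cl$n_detected)
  expect_equal(back$fold_score, round(cl$fold_score, 4))
})
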