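#' Synthetic atlas specification
#'
#' Describes a replicate-level FPKM atlas with known (planted) per-gene
#' specificity categories. Tissue-level mean vectors are built per category
#' so that, in the absence of replicate noise, the classifier recovers the
#' planted category exactly; multiplicative log-normal replicate noise is
#' then layered on top, with a lower dispersion for ubiquitously expressed
#' genes than for the rest (the interindividual-variation contrast).
#'
#' Default category proportions follow the published human-atlas breakdown
#' of 18,684 protein-coding genes (2,359 / 1,208 / 3,227 / 8,385 / 2,484 /
#' 1,021 in canonical category order).
#'
#' @param n_genes Number of genes (default 2000).
#' @param n_tissues Number of tissues (default 32).
#' @param replicates_per_tissue Biological replicates per tissue (default 8).
#' @param category_proportions Six non-negative proportions summing to 1, in
#'   [expression_categories()] order.
#' @param planted_fold Fold separation built into elevated genes; must
#'   exceed `fold` so planted calls survive the inclusive rule (default 10).
#' @param baseline_log_mean,baseline_log_sd Log-normal parameters of the
#'   per-gene expression baseline (defaults `log(10)` and 1, i.e. typical
#'   expressed genes around 10 FPKM spanning roughly one order of magnitude).
#' @param noise_cv_housekeeping Replicate coefficient of variation for
#'   expressed-in-all genes (default 0.1).
#' @param noise_cv_restricted Replicate CV for all other genes (default 0.4).
#' @param sub_cutoff_ceiling Upper bound for "off" tissue values (default
#'   `cutoff / 2`).
#' @param cutoff,fold,group_min,group_max Classifier constants the planted
#'   structure is built against (defaults match [classifier_params()]).
#' @param seed Integer seed; the atlas is a deterministic function of the
#'   spec (per-gene substreams are derived from it, so gene order never
#'   changes any draw).
#' @param structure_seed Optional separate seed for the tissue-level mean
#'   construction. Defaults to `seed`. Two specs sharing a
#'   `structure_seed` but differing in `seed` produce independent noisy
#'   replicates of the same planted truth.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 2000L,
                           n_tissues = 32L,
                           replicates_per_tissue = 8L,
                           category_proportions =
                             c(2359, 1208, 3227, 8385, 2484, 1021) / 18684,
                           planted_fold = 10,
                           baseline_log_mean = log(10),
                           baseline_log_sd = 1,
                           noise_cv_housekeeping = 0.1,
                           noise_cv_restricted = 0.4,
                           sub_cutoff_ceiling = NULL,
                           cutoff = 0.5, fold = 5,
                           group_min = 2L, group_max = 7L,
                           seed = 1L, structure_seed = NULL) {
  n_genes <- as.integer(n_genes)
  n_tissues <- as.integer(n_tissues)
  replicates_per_tissue <- as.integer(replicates_per_tissue)
  if (is.null(sub_cutoff_ceiling)) sub_cutoff_ceiling <- cutoff / 2
  stopifnot(n_genes >= 1L, n_tissues >= 2L, replicates_per_tissue >= 1L,
            length(category_proportions) == 6L,
            all(category_proportions >= 0),
            noise_cv_housekeeping >= 0, noise_cv_restricted >= 0,
            baseline_log_sd >= 0, cutoff > 0)
  if (abs(sum(category_proportions) - 1) > 1e-9) {
    stop("category proportions must sum to 1", call. = FALSE)
  }
  if (planted_fold <= fold) {
    stop("`planted_fold` must exceed the classifier `fold`", call. = FALSE)
  }
  if (sub_cutoff_ceiling <= 0 || sub_cutoff_ceiling >= cutoff) {
    stop("`sub_cutoff_ceiling` must lie in (0, cutoff)", call. = FALSE)
  }

  spec <- structure(
    list(n_genes = n_genes, n_tissues = n_tissues,
         replicates_per_tissue = replicates_per_tissue,
         category_proportions = as.numeric(category_proportions),
         planted_fold = planted_fold,
         baseline_log_mean = baseline_log_mean,
         baseline_log_sd = baseline_log_sd,
         noise_cv_housekeeping = noise_cv_housekeeping,
         noise_cv_restricted = noise_cv_restricted,
         sub_cutoff_ceiling = sub_cutoff_ceiling,
         cutoff = cutoff, fold = fold,
         group_min = as.integer(group_min), group_max = as.integer(group_max),
         seed = as.integer(seed),
         structure_seed = as.integer(
           if (is.null(structure_seed)) seed else structure_seed)),
    class = "synthetic_spec"
  )
  validate_feasibility(spec)
  spec
}

# Parameter inequalities under which the per-category constructions are
# guaranteed to land in their planted category at the tissue-mean level.
# Checked only for categories actually requested, so degenerate proportion
# vectors (e.g. all tissue_enriched) stay usable with few tissues.
validate_feasibility <- function(spec) {
  counts <- apportion_counts(spec$category_proportions, spec$n_genes)
  names(counts) <- expression_categories()
  n <- spec$n_tissues
  f <- spec$fold
  pf <- spec$planted_fold
  if (any(counts[c("group_enriched", "enhanced", "expressed_in_all",
                   "mixed")] > 0) && f <= 2) {
    stop("constructions for non-enriched categories require fold > 2",
         call. = FALSE)
  }
  if (counts[["group_enriched"]] > 0 && n < spec$group_max + 2L) {
    stop(sprintf("group-enriched genes need >= %d tissues",
                 spec$group_max + 2L), call. = FALSE)
  }
  if (counts[["enhanced"]] > 0) {
    m <- spec$group_max + 1L  # moderate tissues: too many for any group
    if (n <= pf || n < m + 2L) {
      stop("enhanced genes need n_tissues > planted_fold and room for the ",
           "high/moderate/low pattern", call. = FALSE)
    }
    if (f * (n - pf) <= pf * m) {
      stop("enhanced construction infeasible: high tissue would exceed ",
           "fold x the moderate level (increase n_tissues or lower ",
           "planted_fold)", call. = FALSE)
    }
    if (f * m < n - pf) {
      stop("enhanced construction infeasible: moderate tissues would ",
           "themselves satisfy the enhanced rule", call. = FALSE)
    }
  }
  if (counts[["mixed"]] > 0 &&
      f * 0.8 * spec$sub_cutoff_ceiling <= 1.9 * spec$cutoff) {
    stop("mixed construction infeasible: off-tissue values too far below ",
         "the detected level (raise sub_cutoff_ceiling)", call. = FALSE)
  }
  invisible(spec)
}

# Largest-remainder apportionment of n items to proportions (deterministic).
apportion_counts <- function(proportions, n) {
  raw <- proportions * n
  counts <- floor(raw)
  deficit <- n - sum(counts)
  if (deficit > 0) {
    take <- order(-(raw - counts))[seq_len(deficit)]
    counts[take] <- counts[take] + 1L
  }
  as.integer(counts)
}

gene_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 129971) %% 2147483629)
}

noise_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 69621 + i * 110503) %% 2147483629)
}

#' Generate a synthetic replicate-level expression atlas
#'
#' Builds one tissue-level mean vector per gene according to its planted
#' category, then expands it to replicates with multiplicative log-normal
#' noise (`mean x LogNormal(0, sigma)`, sigma chosen so the replicate CV
#' equals the spec's housekeeping or restricted level). With zero noise and
#' `planted_fold` above the classifier fold, classifying the aggregated
#' atlas recovers every planted category.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `matrix` (gene x sample numeric matrix), `manifest`
#'   (data.frame `sample_id`, `tissue`) and `truth` (data.frame `gene_id`,
#'   `true_category`, `true_elevated_tissues` semicolon-joined).
#' @export
#' @examples
#' atlas <- generate_atlas(synthetic_spec(n_genes = 50, seed = 7))
#' dim(atlas$matrix)
#' table(atlas$truth$true_category)
generate_atlas <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  validate_feasibility(spec)
  n <- spec$n_tissues
  R <- spec$replicates_per_tissue
  wid <- max(2L, nchar(as.character(n)))
  tissues <- sprintf(paste0("tissue%0", wid, "d"), seq_len(n))
  sample_ids <- as.vector(vapply(tissues, function(t) {
    paste0(t, "_r", seq_len(R))
  }, character(R)))
  manifest <- data.frame(sample_id = sample_ids,
                         tissue = rep(tissues, each = R),
                         stringsAsFactors = FALSE)

  counts <- apportion_counts(spec$category_proportions, spec$n_genes)
  true_cat <- rep(expression_categories(), counts)
  gwid <- max(4L, nchar(as.character(spec$n_genes)))
  gene_ids <- sprintf(paste0("gene%0", gwid, "d"), seq_len(spec$n_genes))

  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }

  vals <- matrix(0, nrow = spec$n_genes, ncol = n * R,
                 dimnames = list(gene_ids, sample_ids))
  elevated <- character(spec$n_genes)
  sigma_hk <- sqrt(log1p(spec$noise_cv_housekeeping^2))
  sigma_rs <- sqrt(log1p(spec$noise_cv_restricted^2))

  for (i in seq_len(spec$n_genes)) {
    set.seed(gene_seed(spec$structure_seed, i))
    built <- build_mean_vector(true_cat[i], spec)
    mu <- built$mu
    elevated[i] <- paste(sort(tissues[built$elevated]), collapse = ";")
    sigma <- if (true_cat[i] == "expressed_in_all") sigma_hk else sigma_rs
    reps <- rep(mu, each = R)
    if (sigma > 0) {
      set.seed(noise_seed(spec$seed, i))
      reps <- reps * stats::rlnorm(n * R, meanlog = 0, sdlog = sigma)
    }
    vals[i, ] <- reps
  }

  list(matrix = vals,
       manifest = manifest,
       truth = data.frame(gene_id = gene_ids,
                          true_category = true_cat,
                          true_elevated_tissues = elevated,
                          stringsAsFactors = FALSE))
}

# Tissue-level mean vector for one gene of the given category. Returns the
# vector plus the indices of the planted elevated tissues. Constructions are
# exact: each satisfies its own category rule and provably violates every
# higher-precedence rule (see the methods vignette for the inequalities).
build_mean_vector <- function(category, spec) {
  n <- spec$n_tissues
  c0 <- spec$cutoff
  pf <- spec$planted_fold
  ceiling0 <- spec$sub_cutoff_ceiling
  baseline <- function() {
    max(stats::rlnorm(1L, spec$baseline_log_mean, spec$baseline_log_sd), c0)
  }

  switch(
    category,
    not_detected = list(mu = stats::runif(n, 0, ceiling0),
                        elevated = integer(0)),
    expressed_in_all = {
      # common baseline x factors in [1, 2): max/min < 2 < fold, so no
      # enrichment rule can fire and every tissue stays detected
      b <- baseline()
      list(mu = b * stats::runif(n, 1, 2), elevated = integer(0))
    },
    tissue_enriched = {
      b <- baseline()
      pick <- sample.int(n, 2L)
      mu <- stats::runif(n, 0, b)
      mu[pick[2L]] <- b                 # runner-up pins max(others) at b
      mu[pick[1L]] <- pf * b
      list(mu = mu, elevated = pick[1L])
    },
    group_enriched = {
      b <- baseline()
      ks <- seq(spec$group_min, spec$group_max)
      k <- ks[sample.int(length(ks), 1L)]
      pick <- sample.int(n, k + 1L)
      grp <- pick[seq_len(k)]
      blocker <- pick[k + 1L]
      mu <- numeric(n)
      mu[grp] <- b * stats::runif(k, 1, 1.2)
      mu[blocker] <- mean(mu[grp]) / pf  # best outsider: exactly pf-fold below
      rest <- setdiff(seq_len(n), pick)
      mu[rest] <- stats::runif(length(rest), 0, mu[blocker])
      list(mu = mu, elevated = grp)
    },
    enhanced = {
      # 1 high tissue, group_max+1 moderate tissues (too many for any group
      # window), the rest low: high = planted_fold x overall mean, yet under
      # fold x the moderate level so neither enrichment rule fires
      m <- spec$group_max + 1L
      pick <- sample.int(n, m + 1L)
      high <- pick[1L]
      mods <- pick[-1L]
      lows <- setdiff(seq_len(n), pick)
      low_vals <- stats::runif(length(lows), 0, ceiling0)
      s <- sum(low_vals)
      a_min <- pf * s / (spec$fold * (n - pf) - pf * m)
      a <- max(baseline(), 1.1 * a_min)
      mu <- numeric(n)
      mu[lows] <- low_vals
      mu[mods] <- a
      mu[high] <- pf * (m * a + s) / (n - pf)  # = planted_fold x mean(all)
      list(mu = mu, elevated = high)
    },
    mixed = {
      ds <- if (n == 2L) 1L else seq(2L, n - 1L)
      d <- ds[sample.int(length(ds), 1L)]
      pick <- sample.int(n, d)
      mu <- ceiling0 * stats::runif(n, 0.8, 1)
      mu[pick] <- c0 * stats::runif(d, 1, 1.9)
      list(mu = mu, elevated = integer(0))
    },
    stop(sprintf("unknown category: %s", category), call. = FALSE)
  )
}

#' Compare a classification against planted truth
#'
#' @param truth Truth table from [generate_atlas()].
#' @param classes Classification data.frame over the same gene universe.
#' @return A list of class `recovery_report`: `overall_accuracy`,
#'   `per_category` (data.frame `category`, `n`, `accuracy`), and
#'   `confusion` (6x6 matrix, rows = truth, columns = assigned).
#' @export
recovery_report <- function(truth, classes) {
  validate_classification(classes)
  stopifnot(is.data.frame(truth),
            all(c("gene_id", "true_category") %in% colnames(truth)))
  if (!setequal(truth$gene_id, classes$gene_id) ||
      nrow(truth) != nrow(classes)) {
    stop("truth and classification cover different gene sets", call. = FALSE)
  }
  assigned <- classes$category[match(truth$gene_id, classes$gene_id)]
  cats <- expression_categories()
  tru <- factor(truth$true_category, levels = cats)
  asg <- factor(assigned, levels = cats)
  confusion <- matrix(as.integer(table(tru, asg)), nrow = 6L,
                      dimnames = list(truth = cats, assigned = cats))
  per_cat <- data.frame(
    category = cats,
    n = as.integer(table(tru)),
    accuracy = ifelse(table(tru) > 0, diag(confusion) / as.integer(table(tru)),
                      NA_real_),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(
    list(overall_accuracy = mean(assigned == truth$true_category),
         per_category = per_cat,
         confusion = confusion),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Category recovery: %.1f%% overall\n",
              100 * x$overall_accuracy))
  df <- x$per_category
  for (i in seq_len(nrow(df))) {
    if (df$n[i] > 0) {
      cat(sprintf("  %-17s n=%5d  %.1f%%\n", df$category[i], df$n[i],
                  100 * df$accuracy[i]))
    }
  }
  invisible(x)
}
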