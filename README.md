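# tissuespec

Classification of protein-coding genes by tissue specificity from bulk
RNA-seq expression atlases, for anyone comparing expression breadth across
a tissue panel: which genes are restricted to one tissue or a small group,
which are expressed everywhere, and how two independently profiled atlases
agree on those calls.

## The classification

Given a gene × tissue matrix of FPKM values, every gene is assigned to
exactly one of six categories using a detection cutoff *c* (default
0.5 FPKM) and an enrichment fold *f* (default 5), evaluated in precedence
order:

| category | rule |
|---|---|
| tissue enriched | some tissue *t*: x_t ≥ c and x_t ≥ f · max of all other tissues |
| group enriched | the top k tissues (k = 2…7) are all ≥ c and mean(top-k) ≥ f · max of the rest |
| tissue enhanced | some tissue *t*: x_t ≥ c and x_t ≥ f · mean over all tissues |
| expressed in all | x_t ≥ c in every tissue |
| mixed | detected somewhere, matching none of the above |
| not detected | x_t < c in every tissue |

All comparisons are inclusive (≥) and multiplicative, so zero references
are legal; the first three categories together are "elevated". Checking
only the top-k tissues for the group rule is provably equivalent to
searching all tissue subsets (the test suite verifies this against
exhaustive enumeration).

Around the classifier the package provides replicate-to-tissue
aggregation, cross-atlas concordance analysis (category cross-tabulation,
expressed-in-all overlap, per-tissue agreement of elevated calls under a
many-to-many tissue mapping), a per-tissue interindividual
coefficient-of-variation comparison between ubiquitously expressed genes
and the rest (Mann–Whitney U), and a synthetic atlas generator with
planted categories and dispersion structure so everything is testable
end-to-end. See the methods vignette
(`vignettes/classification-methods.Rmd`) for the full model and design
rationale.

## Worked example

Classify a single profile across six tissues:

```r
library(tissuespec)
p <- classifier_params()   # cutoff 0.5 FPKM, fold 5, groups 2..7
classify_gene(c(cerebellum = 18.2, cortex = 15.1, liver = 1.3,
                lung = 0.9, skin = 1.1, testis = 2.4), p)
#> $category
#> [1] "group_enriched"
#> $elevated_tissues
#> [1] "cerebellum" "cortex"
#> $fold_score
#> [1] 6.9375
#> $n_detected
#> [1] 6
```

Neither brain tissue alone is fivefold above the other, but together their
mean (16.65) is 6.9-fold above the best remaining tissue (testis, 2.4) —
a group-enriched gene detected in all six tissues.

A full pipeline run on a simulated atlas (2,000 genes × 32 tissues × 8
replicates, planted with the published six-way category proportions):

```r
atlas <- generate_atlas(synthetic_spec(n_genes = 2000, seed = 1))
em <- aggregate_to_tissue(atlas$matrix, atlas$manifest)
cl <- classify_matrix(em)
summarize_classification(cl)
#> Classification of 2000 genes
#>   tissue_enriched      257  (13%)
#>   group_enriched       129  (6%)
#>   enhanced             341  (17%)
#>   expressed_in_all     896  (45%)
#>   mixed                268  (13%)
#>   not_detected         109  (5%)
#>   total elevated       727
#>   elevated genes span 32 tissues

recovery_report(atlas$truth, cl)
#> Category recovery: 99.7% overall
```

The category percentages match the planted proportions, and 99.7% of genes
land back in their planted category despite replicate noise (the handful
of misses sit at the detection boundary). The interindividual variation
analysis on the same atlas:

```r
cv_compare_tissues(atlas$matrix, atlas$manifest, cl)[1, ]
#>     tissue n_expressed_in_all n_other   p_value median_cv_expressed_in_all median_cv_other
#> 1 tissue01                896     534 4.64e-218                     0.0931           0.362
```

Genes expressed in all tissues vary far less between replicates (median
CV 0.09 vs 0.36), detected at vanishing p-values in every tissue — the
planted housekeeping-stability contrast.

A thin command-line wrapper over the same functions ships at
`inst/cli/tissuespec.R` with subcommands `classify`, `compare`, `cv`,
`simulate` and `summarize`.

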