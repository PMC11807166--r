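# agafs — adaptive genetic-algorithm feature selection

`agafs` selects compact feature subsets from high-dimensional
real-valued feature matrices — the kind produced by deep feature
extractors for histopathology images — using an adaptive genetic
algorithm (GA). Its defining trait is the fitness function: instead of
training a classifier for every chromosome (the classical wrapper GA),
chromosome quality can be computed from a minimum-redundancy
maximum-relevance (mRMR) filter score, which makes each generation
cheap. The selected subset is then handed to a KNN classifier (k = 5)
for final classification.

The package is aimed at people post-processing CNN-derived feature
vectors (or any labeled numeric feature table) who want a reproducible,
scriptable selector with honest train/validation/test hygiene.

## The method

A chromosome is a binary vector `agent` over the `d` features
(1 = selected). Its fitness is

```
fitness = α · acc + (1 − α) · (d − Σᵢ agentᵢ) / d ,     α = 0.99
```

where `acc` is either the normalized mean mRMR score of the selected
features (filter mode, default) or KNN validation accuracy on the
selected features (wrapper mode). The mRMR score of feature `f` at
greedy iteration `i` is

```
scoreᵢ(f) = F(f, target) / ( Σ_{s ∈ selected} |corr(f, s)| / (i − 1) )
```

with `F` the one-way ANOVA F statistic (relevance) and `corr` the
Pearson correlation (redundancy). Evolution uses roulette-wheel parent
selection, per-gene crossover (swap probability 0.8), a mutation
probability rising linearly from 0.01 to 0.04 across 60 generations,
and global-best elitism, all driven by one seeded RNG stream so runs
are bit-reproducible.

Also included: the channel-attention operator
`A_c(F) = σ(MLP(GlobalAvgPool(F)) + MLP(GlobalMaxPool(F)))` for
`C × H × W` feature maps, full evaluation metrics (confusion matrix,
accuracy, per-class and macro precision/recall/F1), a Wilcoxon
rank-sum harness for comparing repeated runs, and a synthetic benchmark
generator that plants informative, redundant and noise features.

## Worked example

```r
library(agafs)

# 300 samples, 3 classes, 64 features: 8 informative (separation 5),
# 8 redundant copies, 48 noise; stratified 70/10/20 split
ds <- split_dataset(generate_dataset(synthetic_spec(seed = 1)), seed = 1)

res <- run_ga(ds, ga_config(fitness_mode = "wrapper", seed = 1))
res
#> <fs_result> 12/64 features selected; best fitness 0.998125 after 60
#> generations (1200 fitness evaluations)

report <- knn_classify(ds, res$selected_indices, k = 5)
report
#> <classification_report> accuracy 0.9333
#>         predicted
#> true     class1 class2 class3
#>   class1     19      0      1
#>   class2      0     17      3
#>   class3      0      0     20
#>   class precision recall     f1 support
#>  class1    1.0000   0.95 0.9744      20
#>  class2    1.0000   0.85 0.9189      20
#>  class3    0.8333   1.00 0.9091      20
#> macro: precision 0.9444  recall 0.9333  F1 0.9341
```

The GA compressed 64 features to 12 (the sparsity term of the fitness
rewards smaller subsets once accuracy saturates) and the selected
subset classifies the held-out test split at 93% accuracy. The
`trajectory` element of `res` records the best fitness per generation
and is non-decreasing by construction.

Feature scoring alone:

```r
sc <- mrmr_score_vector(ds)
head(sc$selection_order)   # greedy pick order (1-based column indices)
#> [1] 13 16  9  2  5  8
```

The first picks are informative/redundant columns (columns 1–16 carry
class signal in this benchmark); noise columns rank late.

## Command line

A thin CLI over the same functions ships at `inst/cli/agafs.R`
(requires `optparse`):

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "agafs.R", package = "agafs"))')
Rscript $CLI synth --n-samples 300 --seed 1 --out ds.csv
Rscript $CLI score --in ds.csv --out scores.csv
Rscript $CLI select --in ds.csv --seed 1 --out result.json
Rscript $CLI pipeline --config run.yaml --out-dir runs/demo
```

Commands: `synth`, `score`, `select`, `attend`, `classify`, `compare`,
`pipeline`; every command with randomness takes `--seed`, and
`--version` prints the package version. `pipeline` chains
score → select → classify and writes a manifest (config echo, seeds,
input digest, per-stage output checksums) sufficient to re-run the
analysis identically.

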