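Package: agafs
Title: Adaptive Genetic Algorithm Feature Selection with Filter-Based Fitness
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Feature selection for high-dimensional real-valued feature
    matrices (such as deep features extracted from histopathology images)
    using an adaptive genetic algorithm. Chromosome fitness is computed
    from a minimum-redundancy maximum-relevance (mRMR) filter score
    (one-way ANOVA F statistic for relevance, Pearson correlation for
    redundancy) or, alternatively, from k-nearest-neighbor validation
    accuracy. The genetic algorithm uses roulette-wheel selection,
    per-gene crossover, a linearly increasing mutation schedule and
    global-best elitism. Also provides a standalone channel-attention
    recalibration operator for feature maps, a KNN classifier with full
    evaluation metrics (accuracy, precision, recall, F1, confusion
    matrix), a Wilcoxon rank-sum comparison harness for repeated runs,
    a synthetic benchmark generator with planted informative, redundant
    and noise features, and an end-to-end pipeline driver.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
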