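Package: crosskit
Title: Hybrid-Cross Genomics, Expression and Behaviour Analysis Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of interspecific hybrid crosses between
    two diverged species panels. Provides a forward cross simulator
    (Haldane recombination, backcross pedigrees with marker selection,
    negative-binomial expression counts with cis- and trans-acting
    regulatory effects, ZZ/ZW sex-chromosome contrast, multinomial
    courtship trials), genotype-record quality filters and
    species-diagnostic marker construction, windowed inference of hybrid
    genome composition and Z-linked heterozygosity sexing, simplified
    negative-binomial differential expression with a fold-change plus FDR
    call rule and dual-reference bias control, allele-specific expression
    with cis/trans regulatory classification, frequency-based ABBA-BABA D
    and fd admixture statistics in sliding windows, a multinomial mixed
    model of courtship initiation with Pareto-smoothed importance-sampling
    leave-one-out model comparison, and a configuration-driven pipeline
    tying the stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    vcfR
Config/testthat/edition: 3
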