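Package: ciliowes
Title: Tiered Variant Prioritisation for Consanguineous Ciliopathy Exomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Whole-exome variant prioritisation for consanguineous families
    with suspected ciliopathy. Implements a tiered filtering cascade
    (genotype confidence, population frequency, predicted functional
    effect), autosomal-recessive inheritance selection with
    compound-heterozygote phasing and co-segregation checks, consensus
    in-silico pathogenicity scoring over fixed four-predictor panels,
    runs-of-homozygosity detection from sparse exome genotypes, and
    training-set gene prioritisation by feature similarity with rank
    fusion. Ships a synthetic-cohort generator that produces annotated
    multi-sample VCFs with planted causal variants inside autozygous
    segments so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    jsonlite,
    yaml,
    vcfR,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
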