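Package: gradimmune
Title: Gut Microbiome-Immune Association Modelling Across an Urbanization Gradient
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical machinery for linking gut microbiome composition to
    ex vivo cytokine responses and plasma metabolites across a rural-urban-Western
    gradient of cohorts. Implements a three-group double Wilcoxon gradient screen
    with FDR control, per-microbe pooled log-linear models of cytokine responses
    with Bonferroni-based immunomodulatory classification, species-stratified
    pathway copy-number enrichment models, microbe-metabolite Spearman
    integration with k-means/ARI metabolite clustering, Jensen-Shannon
    compositional distances with a merge-height cluster-count rule, PERMANOVA,
    and metadata association screens. Includes a seeded synthetic-cohort
    generator with planted ground truth for recovery testing, and an end-to-end
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
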