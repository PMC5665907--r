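Package: editaccess
Title: A-to-I RNA Editing, Local RNA Structure, and miRNA-Mediated mRNA Abundance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for adenosine-to-inosine (A-to-I) RNA editing in
    populations of RNA-seq samples: a likelihood-ratio mismatch filter cascade
    for calling editing sites from pileup tables, population editome statistics
    (prevalence, editing index, shared and differential editing, variance in
    editing explained by ADAR expression, sequence-context enrichment),
    partition-function 7-mer accessibility of 3' UTR regions around editing
    sites via ViennaRNA, opposite-nucleotide calling in minimum free energy
    structures, miRNA seed-site matching and editing-to-target distance
    analyses, and a generative model in which AGO2-miRNA complexes
    preferentially degrade the unedited transcript isoform, buffering observed
    editing levels. Includes a synthetic-data module that simulates hairpin
    3' UTRs, population expression profiles, editing-dependent degradation and
    pileup-level read sampling for end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: ViennaRNA (RNAfold and RNAplfold executables on the PATH)
Config/testthat/edition: 3
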