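Package: mutasym
Title: Mutation Spectra, Strand Asymmetry, and Mutagenesis Assay Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of mutation-accumulation experiments in budding yeast
    exposed to alkylating agents. Reads per-sample mutation catalogs (VCF or
    TSV), applies depth and allele-support call filters, removes recurrent
    calls, and clusters nearby mutations into complex events. Computes
    purine-keyed substitution spectra, per-genome mutation burdens, and
    event-class fractions; profiles transcriptional strand asymmetry across
    fractional transcript bins with flanking bins and replicative strand
    asymmetry across fractional inter-origin bins with linear-regression
    trends. Estimates mutation rates from Luria-Delbruck fluctuation assays
    (Lea-Coulson method of the median), converts colony counts to survival
    percentages and fold-rescue values, and fits equilibrium fluorescence
    anisotropy titrations to the quadratic one-site (ligand-depletion)
    binding model. Includes a synthetic-data generator producing toy genomes,
    annotations, mutation catalogs with injected strand biases, fluctuation
    counts, and noisy titrations with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    VariantAnnotation,
    SummarizedExperiment,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'mutasym-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'binding-fit.R'
    'catalog-io.R'
    'catalog-filter.R'
    'cluster.R'
    'colony-assays.R'
    'spectrum.R'
    'strand-asymmetry.R'
    'synthetic-genome.R'
    'synthetic-catalog.R'
    'synthetic-assays.R'
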