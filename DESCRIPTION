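Package: rtkpair
Title: Receptor Tyrosine Kinase Ligand-Receptor Pair Prediction from Sequence and Domain Features
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts interacting receptor tyrosine kinase (RTK) / growth-factor
    ligand pairs from amino-acid sequences. Protein pairs are encoded as k-mer
    composition vectors (1-mer, 2-mer), binary conserved-domain and superfamily
    presence vectors, or a composite of both, and classified with a
    class-weighted C-SVM that compensates the strong positive/negative
    imbalance of all-against-all pair datasets. Includes redundancy reduction
    by greedy identity clustering, exhaustive negative-pair enumeration,
    stratified repeated cross-validation and independent-test protocols with
    precision/recall/F-measure/ROC/AUC reporting, AUC-weighted combination of
    two models' decision values, and a seeded synthetic-data generator that
    emulates the structure of RTK-ligand interaction datasets so the whole
    pipeline is testable without database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    S4Vectors,
    e1071
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Classification, Proteomics, SupportVectorMachine, NetworkInference
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'cli.R'
    'dataset.R'
    'evaluate.R'
    'featurize.R'
    'model.R'
    'rtkpair-package.R'
    'seqio.R'
    'synthdata.R'
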