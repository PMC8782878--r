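Package: divpick
Title: Diverse Molecule Selection by Log-Determinant Submodular Maximization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Selects diverse subsets of molecules from a candidate list by
    greedily maximizing a log-determinant submodular function of molecular
    descriptor vectors, with the classical MaxMin, MaxSum and random pickers
    as baselines. Diversity of a selection is evaluated both with a
    property-based criterion (the Wasserstein distance of selected property
    values to a uniform distribution, WDUD) and with the standard
    structure-based criterion (mean pairwise Tanimoto dissimilarity of MACCS
    keys or ECFP fingerprints). Includes readers and writers for SMILES
    lists, descriptor matrices and property tables, derived-property
    transforms that weaken system-size dependence of energetic properties,
    and synthetic fixture generators emulating ReLU-normalized embedding
    vectors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, jsonlite, ChemmineOB, yaml, optparse
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'io.R'
    'descriptors.R'
    'logdet.R'
    'baselines.R'
    'wdud.R'
    'property_eval.R'
    'synthetic.R'
    'cli.R'
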