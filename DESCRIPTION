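Package: domainsweep
Title: Per-Residue Protein Domain Prediction with mRMR Feature Selection
        and Random Forests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
        role = c("aut", "cre"))
Description: Predicts, residue by residue, whether each position of a
        protein sequence lies inside a structural domain. Residues are
        encoded as sliding windows of 31 per-position features (20 PSSM
        conservation scores, an intrinsic disorder score, the five
        Atchley amino-acid factors, 3-state secondary structure and
        2-state solvent accessibility), ranked by minimum-redundancy
        maximum-relevance mutual information, classified by an ensemble
        of fully grown decision trees on bootstrap replicates, winnowed
        by incremental feature selection under 5-fold cross-validation,
        and finally smoothed by a run-length scanning refinement that
        turns per-residue calls into contiguous domain regions. A
        synthetic data generator with class-conditional feature signal
        makes the whole pipeline testable without external predictors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, Rcpp, Biostrings, IRanges, S4Vectors,
        jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse, yaml, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 'RcppExports.R' 'atchley.R' 'AllClasses.R' 'sequence-io.R'
        'encoding.R' 'mrmr.R' 'forest.R' 'ifs.R' 'refine.R'
        'synthetic.R' 'pipeline.R' 'domainsweep-package.R'
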