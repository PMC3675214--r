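Package: pepdesign
Title: Combinatorial Peptide Inhibitor Design with Free-Energy Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for designing groove-binding peptide inhibitors of amyloid
    fibrils by chemically restricted combinatorial mutagenesis. Enumerates
    single-residue substitutions of a reference peptide within chemical
    groups, grows an inhibitor candidate library by recursively combining and
    scoring mutation sets, and rescores the library with a second scoring
    function. Final candidates are assessed by estimating potentials of mean
    force from constant-velocity pulling work traces via Jarzynski's equality
    under the stiff-spring approximation, with cumulant and bootstrap options.
    Includes an overdamped Langevin pulling simulator that provides analytic
    ground truth for validating the free-energy estimators, pluggable scorer
    contracts for externally computed docking scores, and readers and writers
    for FASTA peptide libraries, score tables, and pulling-trace files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, Biostrings, yaml
Suggests: testthat (>= 3.0.0), jsonlite, optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'amino-acids.R'
    'AllClasses.R'
    'AllGenerics.R'
    'mutations.R'
    'scorers.R'
    'search.R'
    'pmf.R'
    'smd.R'
    'io.R'
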