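Package: pwmtree
Title: Phylogeny-Guided Sequence Classification with Trees of Position
    Weight Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Maximum-likelihood taxonomic classification of protein or
    nucleotide sequences against a user-supplied reference set. A model is
    trained from a gapped multiple alignment of reference sequences and a
    phylogeny of the reference taxa: every node of the phylogeny receives a
    position-specific weight matrix (PWM) over the alignment columns, with
    the gap treated as an ordinary character. Queries are aligned once to
    the root PWM by semi-global dynamic programming (local in the query,
    global in the PWM) and then classified by greedy descent through the
    PWM tree, reporting a log10 evidence ratio at every decision. Includes
    Henikoff position-based sequence weighting to reduce sampling bias,
    leave-one-out cross-validation to estimate the error rate, a binary
    model format, a deterministic synthetic reference-set generator for
    testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    ape,
    optparse
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'alphabet.R'
    'AllClasses.R'
    'io-fasta.R'
    'io-newick.R'
    'io-model.R'
    'weighting.R'
    'pwm.R'
    'train.R'
    'align.R'
    'classify.R'
    'xval.R'
    'fixtures.R'
    'cli.R'
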