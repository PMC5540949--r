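Package: ampliforge
Title: Mock-Community-Validated 16S rRNA Amplicon OTU Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A self-contained 16S rRNA gene amplicon analysis pipeline: paired-end
    read merging with posterior quality scores, primer trimming, expected-error
    filtering, dereplication with singleton removal, greedy centroid OTU clustering
    with de novo chimera flagging, naive-Bayes k-mer taxonomy with bootstrap
    confidence, rarefaction, alpha and beta diversity, UPGMA sample trees, PCoA and
    NMDS ordination, AMOVA and HOMOVA permutation tests, and OTU co-occurrence
    networks exported as GEXF. Includes a mock-community read simulator (equal-cell,
    equal-protein and uneven community designs with 16S copy-number weighting,
    Illumina-like substitution errors and between-sample index cross-talk) used to
    validate every stage end to end, plus a detector for cross-talk between
    multiplexed samples.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    ape,
    MASS,
    xml2,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
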