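Package: radasm
Title: Local De Novo Assembly of Overlapping Paired-End RAD Loci
Version: 0.1.0
Authors@R: person("radasm", "maintainers", email = "radasm@example.org", role = c("aut", "cre"))
Description: Clusters restriction site-associated DNA (RAD) forward reads into
    loci within and across individuals, selects optimal clustering mismatch
    thresholds, sorts paired reverse reads per locus with data reduction, and
    performs a two-step greedy overlap-layout-consensus assembly of each locus
    into RAD contigs.  Includes a diploid RAD-seq read simulator with in-silico
    restriction digest and ground-truth labels, read-pair quality-control
    filters, and evaluation metrics (N50, re-mapping proper-pair rates, and
    identity against simulated truth).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    jsonlite,
    parallel,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
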