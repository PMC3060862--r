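Package: flankscan
Title: Motif Architecture of the Regions Flanking a Conserved Protein Domain
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting the amino- and carboxy-terminal regions
    that flank a highly conserved core domain in a protein family, built
    around the HD-Zip subfamily I transcription factors. Partitions each
    protein into NTR, core HD-Zip domain and CTR from profile-HMM domain
    hits; compiles and scans degenerate PROSITE-style consensus patterns
    (such as the sumoylation consensus Psi-K-x-[ED]) with canonical versus
    control enrichment statistics; profiles positional residue composition
    (decile histograms); computes alignment column conservation, position
    frequency matrices and information content for sequence logos; maps
    externally discovered motif occurrences onto regions with
    proximal/distal placement, group specificity, AHA-likeness features
    and overlap with phosphorylation/NLS predictions; and simulates
    protein families with planted ground truth so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    yaml,
    withr,
    ggplot2,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
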