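Package: openadj
Title: Open Adjacencies and k-Breaks: Detecting Simultaneous Rearrangements
    in Cancer Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects simultaneous multi-break rearrangements (chromothripsis,
    chromoplexy) in cancer genomes from somatic novel adjacencies and a
    copy-number segmentation. Matches breakends into counterpart pairs, maps
    copy-number segment boundaries to breakends as a signed step function,
    classifies adjacencies as open via counterpart-asymmetry or copy-number
    asymmetry, and summarises adjacency sets with the open adjacency rate
    (OAR) and the copy-number asymmetry enrichment (CAE). Includes a k-break
    rearrangement simulator with ground-truth event labels for validation,
    plus BEDPE/SEG readers and writers and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
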