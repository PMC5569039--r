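Package: wrkyscan
Title: Genome-Wide WRKY Transcription-Factor Family Identification and
    Target-Gene Survey
Version: 0.1.0
Authors@R:
    person("wrkyscan", "developers", email = "wrkyscan@example.org",
           role = c("aut", "cre"))
Description: Identifies WRKY transcription-factor family members in a
    proteome by detecting the WRKY heptapeptide domain (WRKYGQK and
    variants) and its downstream CX(a)CX(b)HXH/C/Y zinc-finger spacing
    signature, classifies members into groups I, IIa-IIe, III and a
    non-group by structural rules plus nearest-reference identity, and
    builds bootstrapped Neighbor-Joining trees from an internally
    computed progressive alignment.  Extracts 1-kb upstream regulatory
    regions from a genome plus GFF3 annotation, scans both strands for
    the W-box (YTGACY) and a PLACE-style cis-element catalog, and calls
    potential WRKY target genes by W-box count tiers.  Calls
    differential expression from qPCR Ct tables (2^-ddCt with ANOVA and
    Dunnett many-to-one testing) and from RNA-seq fragment counts (FPKM
    thresholds with bootstrap deviation probability).  A synthetic-data
    module generates proteomes, annotated genomes and expression tables
    with recorded ground truth so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
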