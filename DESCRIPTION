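Package: ringzf
Title: Rule-Based Detection and Classification of RING Zinc-Finger Domains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable, fully testable pipeline for genome-wide surveys of
    RING-type zinc-finger (E3 ubiquitin ligase) gene families, modeled on the
    hexaploid wheat family survey workflow. Locates RING domains by an
    eight-metal-ligand rule engine over explicit consensus spacings and
    classifies them into subtypes (RING-H2, RING-HCa/HCb, RING-D, RING-M, plus
    the accessory IBR domain); computes standard physicochemical protein
    properties (molecular weight, isoelectric point, GRAVY, aliphatic and
    instability indices, atomic composition); estimates Ka/Ks by the
    Nei-Gojobori (1986) pathway-counting method with Jukes-Cantor correction
    and converts Ks to divergence time; reduces redundancy by greedy identity
    clustering and builds neighbor-joining trees with bootstrap support; scans
    promoters for IUPAC cis-regulatory elements; and derives expression groups
    and qPCR 2^-ddCt fold changes from TPM and CT tables. Every pipeline input
    can be simulated with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    IRanges,
    ape,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
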