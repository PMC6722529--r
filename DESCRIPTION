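Package: codonbias
Title: Synonymous Codon Usage Bias and Virus-Host Adaptation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing synonymous codon usage bias in coding
    sequences: nucleotide and positional composition, relative synonymous
    codon usage (RSCU), Wright's effective number of codons (ENC) with the
    GC3s expected curve, parity rule 2 (PR2) plots, neutrality (GC12 on GC3)
    regression, codon adaptation index (CAI), relative codon deoptimization
    index (RCDI), similarity index (SiD) against host reference codon usage
    tables, principal component analysis of RSCU profiles, and Spearman
    correlation summaries.  Includes a synthetic coding-sequence generator
    with controllable mutational third-position bias and host-directed
    translational selection, and a one-command pipeline that emits
    plot-ready tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    seqinr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
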