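Package: stateseq
Title: Single-Neuron CEL-Seq2 Quantification and Drosophila Sleep-Metabolism Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for studying how feeding state reshapes
    gene expression and sleep in Drosophila. One arm reconstructs single-neuron
    transcriptomes from CEL-Seq2-style paired-end reads: barcode demultiplexing,
    3'-tag transcript assignment, directional UMI deduplication, spike-in based
    cell quality control, TPM normalisation, and a negative-binomial Wald test
    for fed-versus-starved differential expression with hypergeometric gene-set
    over-representation. The other arm scores sleep from Drosophila Activity
    Monitor (DAM) beam-crossing traces using the 5-minute immobility rule,
    estimates Markov sleep/wake drive (P(doze), P(wake)), and computes
    within-fly starvation-induced sleep suppression with the standard group
    comparisons. A synthetic-data generator produces sequencing libraries and
    behavioral traces with known ground truth so the entire pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    fgsea,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse
Config/testthat/edition: 3
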