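Package: mamutspec
Title: Mutation-Accumulation Rate and Spectrum Analysis for Bacterial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of bacterial mutation-accumulation (MA)
    experiments. Generates synthetic GC-rich genomes with coding annotation,
    plants base substitutions and short indels with a configurable six-class
    spectrum, methylation-motif and CpG hotspots and SSR-biased slippage, and
    emits per-line pileup allele counts with sequencing error. Calls fixed
    mutations by the line-versus-consensus approach, estimates per-site
    per-generation mutation rates with exact Poisson confidence intervals,
    computes conditional spectra, transition/transversion ratios, the
    mutational-equilibrium GC content, a nonsynonymous/synonymous selection
    test against a codon-usage expectation, and motif/CpG hotspot enrichment
    and indel SSR-context summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    GenomicRanges
Config/testthat/edition: 3
RoxygenNote: 7.3.3
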