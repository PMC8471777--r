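Package: agpminer
Title: Mining and Profiling of Hydroxyproline-Rich Glycoproteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mining arabinogalactan proteins (AGPs) and other
    hydroxyproline-rich glycoproteins (HRGPs) from predicted proteomes and
    for profiling their expression. Implements a secretion and
    hydroxyproline filtering funnel, hydroxyproline-aware arabinogalactan
    glycomodule scanning under relaxed and strict clustering rules, motif
    and amino acid bias (MAAB) classification, chimeric-AGP architecture
    annotation (fasciclin-like, kinase-like and AG peptide families,
    mature-peptide derivation, membrane topology), an alignment-free 3-mer
    neighbor-joining phylogeny with bootstrap support and low-support
    collapsing, and qPCR delta-delta-Ct expression statistics with joint
    Benjamini-Hochberg correction, Pearson correlation clustering and
    jackknife bias-corrected mutual information. A synthetic-data module
    generates proteomes with planted HRGP structure and qPCR Ct tables
    with planted effects so every stage can be tested end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
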