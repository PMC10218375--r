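Package: mutaspec
Title: Dose-Response Fitting and Genome Mutation-Spectrum Analysis for Mutagenized Plant Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for physical-mutagenesis experiments in crops: fits the
    single-hit multitarget (SHMT) model to irradiation survival and fertility
    curves, derives shoulder doses (Dq), 50%-effect doses and relative
    biological effectiveness (RBE) between mutagens, and implements a
    mutation-spectrum pipeline for whole-genome resequenced mutant lines:
    allele-frequency and genotype based zygosity classification, control
    subtraction, cross-line shared-variant exclusion, merging of adjacent
    single-base substitutions into multinucleotide variants, scaffold
    structural-variant filtering, spectrum summaries (SBS, INDEL, MNV, SV),
    Ts/Tv ratios, gene-effect summaries and the cross-mutagen statistical
    tests. Includes a synthetic-data generator with ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
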