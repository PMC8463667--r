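Package: mitomix
Title: Quantification of Exogenous Mitochondrial DNA Mixtures, Deletion
    Heteroplasmy and Mitochondrial Content
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimators and matched simulators for measuring mitochondrial
    augmentation: percent exogenous mtDNA from informative-SNP allele
    frequencies in sequencing pileups over a circular mitochondrial
    reference, absolute copy number and large-deletion heteroplasmy from
    digital-PCR partition counts via Poisson occupancy statistics, and the
    fraction of exogenous mitochondrial content from per-cell two-channel
    fluorescence. A synthetic-data generator produces haplotype pairs,
    paired-end reads with truth alignments, digital-PCR chips and
    fluorescence panels with known ground truth for parameter-recovery
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    jsonlite,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
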