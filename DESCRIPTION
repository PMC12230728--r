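Package: varoff
Title: Variant-Aware CRISPR Off-Target Site Search on Phased Haplotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finds CRISPR guide-RNA potential off-target sites not only on a
    reference genome but on each phased haplotype of an individual. From a
    reference FASTA and a phased single-sample VCF the package decomposes,
    left-aligns and splits variants per haplotype, reconstructs each allelic
    sequence together with an invertible reference/haplotype coordinate map,
    scans reference and haplotypes for spacer+PAM matches within a mismatch
    budget (IUPAC-degenerate PAM, both strands), and classifies sites as
    shared, allele-gained or allele-lost with coordinates mapped back to the
    reference where possible. Includes a seeded synthetic genome/VCF fixture
    generator with planted gain/loss sites, a YAML PAM catalog, and a
    command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    vcfR,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
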