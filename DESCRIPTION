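Package: tetrasnp
Title: SNP Discovery and HRM Genotyping in Allotetraploid Amplicon Panels
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for single-nucleotide polymorphism (SNP) discovery in
    allotetraploid species by Sanger amplicon sequencing against the two
    diploid progenitor genomes. Models the amplicon consensus of superposed
    subgenome copies with IUPAC ambiguity codes, infers per-locus subgenome
    copy composition, and classifies every variable site as a homologous SNP,
    a homoeologous sequence variant (HSV) between subgenomes, or a paralogous
    sequence variant (PSV) within a subgenome. Includes a ground-truth panel
    simulator, marker statistics (polymorphism information content, variant
    densities, strand-collapsed variant-class spectra, linkage-disequilibrium
    r-squared, recombinant-inbred-line segregation tests), and a simplified
    high-resolution-melting (HRM) engine for melt-curve genotyping.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
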