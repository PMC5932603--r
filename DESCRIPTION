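Package: polyorf
Title: Alternative Open Reading Frames, Silent-but-Altering Variants, and
    Frame-Specific Conservation Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the polycistronic view of mature transcripts:
    enumerate and classify alternative open reading frames (uORFs, dORFs,
    overlapping and lncRNA ORFs) under an ATG-start, 30-codon-minimum
    definition; re-annotate single-nucleotide variants in every reading
    frame to flag variants that are synonymous in the canonical frame but
    alter an alternative protein; test the fraction of canonical-synonymous
    variants hitting alternative ORFs against a stratified permutation
    null; and detect frame-specific purifying-selection periodicity in
    per-base conservation tracks with Haar-wavelet denoising. Includes a
    seeded synthetic-data generator (transcripts with planted alternative
    ORFs, conditioned synonymous variant sets, conservation tracks) that
    emits ground truth for every fixture, plus readers and writers for
    FASTA, GFF3, VCF and bedGraph.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    rtracklayer,
    vcfR,
    jsonlite,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
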