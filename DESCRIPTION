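Package: flanktag
Title: Validation and Genomic Mapping of Insertional-Mutant Flanking Sequence Tags
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bulk processing of flanking sequence tags (FSTs) from T-DNA or
    transposon insertional mutagenesis. Reads FASTA, FASTQ, or zipped PHD
    input with modified-Mott quality trimming; locates and masks transgene
    border, PCR adaptor, and vector-backbone sequence within each read;
    classifies reads as acceptable, too short, vector, or low quality; maps
    acceptable tags to a reference genome with a built-in seeded local
    aligner (Karlin-Altschul e-values, exact Smith-Waterman oracle, optional
    external BLASTN); categorizes each insertion by genomic context (exon,
    intron, 5' upstream, 3' downstream, intergenic, repeat) against GFF3 or
    BED12 gene models; and reports per-chromosome counts, sliding-window
    insertion frequencies, and distribution figures. Includes a deterministic
    synthetic-data generator with ground truth for end-to-end verification.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    withr,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
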