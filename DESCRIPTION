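Package: neotel
Title: Detection and Characterization of Alternative Lengthening of
    Telomeres from Sequencing Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting and characterizing alternative lengthening
    of telomeres (ALT) in tumor sequencing data: classification of telomeric
    and satellite repeat reads, GC-normalized telomere content estimation,
    calling of telomeric repeat loci (neo-telomere junctions) from discordant
    and split reads with panel-of-normals filtering, microhomology scoring at
    junctions, copy-number association, two-sided event pairing, TERRA and
    ChIP repeat enrichment quantification, C-Circle positivity calling,
    telomere-maintenance-mechanism subgrouping, and cohort association
    statistics.  A deterministic simulator generates alignment-level inputs
    with implanted junctions and full ground truth so the whole pipeline can
    be exercised without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    Rsamtools,
    GenomicRanges,
    IRanges,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
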