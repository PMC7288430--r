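Package: viroscreen
Title: Recovery and Curation of Free and Integrated Viruses from
    Metagenomic Assemblies by Annotation Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies bacterial and archaeal viruses (free virions and
    integrated proviruses) among assembled metagenomic scaffolds using a
    hybrid of per-profile virus-association scores (v-scores) derived from
    HMM annotation signatures and a small neural-network classifier, with
    automated curation, provirus excision at host-like annotation runs,
    circularity and draft-quality estimation, lytic/lysogenic labelling,
    and auxiliary-metabolic-gene (AMG) profiling. Includes a deterministic
    synthetic-data generator so the whole workflow is testable without
    external profile databases, and a benchmark-metric calculator with
    class-size normalization.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, Biostrings, nnet, jsonlite
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
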