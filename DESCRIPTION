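Package: secmdecon
Title: Methylation-Based Decontamination and Aneuploidy Calling for
    Noninvasive Preimplantation Genetic Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Enriches blastocyst DNA in spent embryo culture medium (SECM)
    bisulfite sequencing data by selecting fully unmethylated multi-CpG
    reads, and calls whole-chromosome copy-number aneuploidy with a
    two-stage (pre-/post-decontamination) threshold rule. Includes a
    per-read methylation profiler, a contamination mixture simulator with
    cell-type methylation signatures and karyotypes, a Ginkgo-style binned
    copy-number caller with lowess GC correction, and the concordance
    statistics (GCR, FNR, FPR, SDR) used to benchmark SECM calls against
    trophectoderm biopsy results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
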