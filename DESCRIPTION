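Package: unsense
Title: Substitution-Space Analytics and Evidence-Driven Classification of
    Synonymous and Unsense Coding Variants
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for looking beyond the genetic code when annotating
    coding single-nucleotide variants. Exhaustively enumerates and
    summarises the single-base substitution space of a codon table
    (transitions/transversions, synonymous, missense, nonsense, stop-loss
    and stop-to-stop changes, wobble-position analysis), classifies
    variants that look synonymous at codon level into verified-synonymous,
    synonymous-with-effect and unsense categories using experimental
    evidence records rather than sequence-based prediction, applies
    frame-retention and nonsense-mediated-decay escape rules to splicing
    consequences, audits variant files for evidence-free "synonymous"
    claims, and generates fully seeded synthetic fixtures (transcript
    models, coding sequences, variants, planted evidence) so the whole
    pipeline is testable offline. Includes parsers and writers for a
    minimal HGVS c. substitution subset, transcript models as JSON or a
    GFF3 subset, evidence tables, codon tables and VCF annotation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    jsonlite,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
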