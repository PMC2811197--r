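Package: bromoscope
Title: Family-Wide Profiling of Bromodomain Histone-Binding Selectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for profiling acetyl-lysine recognition across a bromodomain
    family. Builds centred 15-residue acetyl-lysine histone peptide libraries
    from annotated acetylation sites, quantifies and normalizes dot-blot
    membranes against GST calibration spots, computes molecular interaction
    fields (probe grid energetics) over superposed binding sites, classifies
    domains into histone binders and non-binders by the first principal
    component of block-scaled field matrices, clusters domains by
    neighbor-joining, and maps component loadings back to binding-site regions
    and chemical probes. Includes seeded synthetic generators for membranes,
    binding matrices and pocket scaffolds so every stage is testable end to
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
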