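Package: wmms
Title: Multiparametric Missense Mutation Scoring for Preclinical Disease
    Models
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: In-silico saturation mutagenesis and multiparametric severity
    scoring of missense mutations in a coding sequence, developed around
    glycine decarboxylase (GLDC) and non-ketotic hyperglycinemia (NKH).
    Enumerates every theoretical missense mutation reachable by a single
    nucleotide substitution, scores each against a registry of binary
    structural, evolutionary and biochemical parameters (MMS), trains
    clinically weighted parameter coefficients against clinical outcome
    scores (WMMS), maps mutations between orthologous proteins through a
    pairwise alignment, ranks candidates for attenuated and severe mouse
    disease models, and predicts prenatal lethality and postnatal
    hydrocephalus from the weighted score, with Mendelian genotype-ratio
    statistics for breeding colonies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    yaml,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
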