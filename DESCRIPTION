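Package: rxscreen
Title: Rule-Based Medication Safety Screening at Prescription Time
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An evaluation engine for prescription-time detection of
    medication-related problems (MRPs): drug-drug interactions, therapeutic
    duplications, regulatory safety contraindications (including the
    nephrotoxic "Triple Whammy" combination), potentially inappropriate
    medication for patients aged 75 and over, contraindications due to
    health problems or clinical variables, teratogens in pregnancy,
    anticholinergic combinations, and suspected hypersensitivity or adverse
    drug reaction history. Rules are configured as typed CSV tables over ATC
    drug groups and ICD-10 problem groups. The package also provides an
    append-only audit log with alert-acceptance semantics, reporting of
    generated/accepted alert tables and rankings, a synthetic
    prescription-stream generator with planted conflicts for validation,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
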