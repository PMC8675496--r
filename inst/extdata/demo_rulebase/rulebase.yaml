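version: demo-2018
counts:
  interactions: 5
  duplications: 7
  aemps: 14
  geriatrics: 15
  problem_contra: 2
  clinical_vars: 2
  teratogens: 1
  anticholinergics: 1
  sensitivity: 5
files:
  - formulary.csv
  - drug_groups.csv
  - problem_groups.csv
  - interactions.csv
  - duplications.csv
  - aemps.csv
  - geriatrics.csv
  - problem_contra.csv
  - clinical_vars.csv
  - teratogens.csv
  - anticholinergics.csv
  - sensitivity.csv
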