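# rxscreen

Rule-based medication safety screening at prescription time.

## The problem

When a clinician starts a new drug for a patient, most preventable harm is
already visible in the record: a concomitant drug that interacts with the
candidate, a therapeutic duplication, a nephrotoxic combination such as the
**Triple Whammy** (NSAID + renin–angiotensin-system inhibitor + diuretic),
a potentially inappropriate medicine for a patient aged ≥ 75, a
contraindicating diagnosis or laboratory value, a teratogen in pregnancy,
an anticholinergic pile-up, or a recorded hypersensitivity or adverse drug
reaction. `rxscreen` implements the evaluation core of a primary-care
clinical decision support system (CDSS) that screens every candidate
prescription against nine families of medication-related problems (MRPs)
and returns an ordered, severity-coded alert screen — **RED** for absolute
contraindications, **ORANGE** for precautionary warnings.

The package is written for pharmacoepidemiologists and CDSS engineers who
want a transparent, auditable, fully configurable alerting engine plus the
analytics layer needed to study **alert acceptance**: an alert counts as
*accepted* only when the medicine that generated it was not prescribed;
continuing the drug with a dose reduction or a follow-up order does not
count.

## What is inside

| Layer | Functions |
|---|---|
| Terminology | `parse_atc()`, `parse_icd10()`, `atc_in_group()`, `icd10_in_group()`, `product_in_group()` — ATC/ICD-10 normalization and prefix-based group membership |
| Patient model | `patient_record()`, `prescription()`, `age_at()`, `active_prescriptions()` (half-open `[start, end)` intervals), `latest_measurement()`, JSON-Lines I/O |
| Rulebase | `load_rulebase()`, `validate_rulebase()`, `write_rulebase()`, `demo_rulebase()` — nine typed rule families configured as CSV tables over ATC drug groups and ICD-10 problem groups |
| Engine | `evaluate()` and ten per-family checkers; `assemble_screen()` orders RED before ORANGE with a fixed family order and deduplicates on (rule, conflicting entity) |
| Audit | `record_episode()`, `is_accepted()`, `read_audit()` / `write_audit()` — append-only JSONL episode log with the acceptance semantics above |
| Reporting | `pct()` / `share()` (integer %, half away from zero), `aggregate_alerts()` (family × year generated/accepted tables), `top_alerts()` rankings, `load_printed_fixture()` |
| Simulation | `sim_config()`, `generate_population()`, `generate_episode_stream()`, `evaluate_recovery()` — seeded synthetic cohorts with planted single-family conflicts and a stochastic prescriber-acceptance model |
| CLI | `rxscreen_main()` with subcommands `validate-rules`, `evaluate`, `report`, `simulate` (wrapper script in `inst/exec/rxscreen`) |

## Worked example

A 77-year-old man on acetylsalicylic acid, enalapril and furosemide;
the clinician starts ibuprofen:

```r
library(rxscreen)
rb <- demo_rulebase()
patient <- patient_record("P001", birth_date = "1941-02-10", sex = "M",
  prescriptions = list(
    prescription("rx1", "acetylsalicylic_acid", start_date = "2017-03-01"),
    prescription("rx2", "enalapril",            start_date = "2016-11-15"),
    prescription("rx3", "furosemide",           start_date = "2017-01-20")))
screen <- evaluate("ibuprofen", patient, rb, "2018-06-01")
print(screen)
#> <alert screen: 3 alert(s)>
#>   [RED] A-TRIPLE-WHAMMY  aemps        ibuprofen | Concomitant NSAID with a renin-angiotensin system inhibitor and a diuretic markedly increases the risk of acute kidney injury
#>   [ORANGE] I-NSAID-ASA      interactions ibuprofen | NSAIDs blunt the antiplatelet effect of acetylsalicylic acid and increase gastrointestinal bleeding risk
#>   [ORANGE] G-NSAID          geriatrics   ibuprofen | NSAIDs and COXIBs carry renal gastrointestinal and cardiovascular risk in patients aged 75 and over
```

The screen contains one absolute contraindication (the Triple Whammy,
ordered first) and two precautionary alerts. If the clinician abandons the
prescription, the audited episode counts as accepted:

```r
ev <- record_episode("ibuprofen", screen, "not_prescribed", "2018-06-01", "P001")
is_accepted(ev)
#> [1] TRUE
pct(1222159, 4379866)   # three-year overall acceptance of the reference deployment
#> [1] 28
```

From the shell, the same pipeline:

```sh
rxscreen simulate --config sim.yaml --out run/
rxscreen evaluate --rules rules/ --patients run/population.jsonl \
                  --episodes run/episodes.jsonl --out run/audit.jsonl
rxscreen report --audit run/audit.jsonl --format markdown
```

## Limitations

The bundled rulebase is demonstration content covering only publicly named
drugs and groups — it is not a clinical knowledge base, and the package is
not a medical device. See the methods vignette
(`vignettes/medication-safety-screening.Rmd`) for the model, its
assumptions, and design decisions.
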