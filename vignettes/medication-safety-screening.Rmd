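---
title: "Prescription-time medication safety screening: model, content and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prescription-time medication safety screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxscreen)
```

## The screening model

`rxscreen` evaluates one candidate prescription against one patient record
at one date. The evaluation is one-directional: the candidate is screened
against the existing record; previously co-prescribed drugs are never
re-screened against each other. The engine is advisory — it returns an
alert screen, never a block — and is a pure function of (candidate,
patient, rulebase, date), which is what makes every downstream statistic
reproducible.

Nine MRP (medication-related problem) families are screened, each with its
own checker and typed rule schema:

1. **Drug–drug interactions** — unordered pairs of drug groups; an alert
   fires per (rule, conflicting active prescription), whichever of the two
   groups the candidate falls in, and the alert names the concrete
   conflicting product. Ingredient-level attribution passes through fixed
   combinations: a rule written against tramadol fires for a
   tramadol-with-paracetamol combination product.
2. **Therapeutic duplications** — two prongs: same-ingredient duplication
   is intrinsic (it needs no configured content, because ingredient
   identity is not a knowledge-base judgement), while
   same-pharmacological-action duplication uses configured groups. Each
   configured group is subtyped `clinically_relevant` or `dose_adjustment`
   — the latter marks combinations often sought deliberately (e.g.
   renin–angiotensin-system inhibitor dose titration), whose alerts are
   expected to be ignored more often.
3. **Regulatory (AEMPS-style) safety alerts** — always RED, expressed as a
   trigger group plus optional required co-medication groups, age bounds,
   problem groups and a daily-dose threshold. The Triple Whammy is plain
   content in this schema (trigger: NSAIDs; required co-medication:
   renin–angiotensin-system inhibitors and diuretics), not a special case.
4. **Potentially inappropriate medication in old age** — always ORANGE,
   firing at completed age ≥ 75 (the content's cut-off; `validate_rulebase()`
   warns on any other value).
5. **Contraindications due to health problems** (ICD-10 problem groups)
   and **due to clinical variables** (e.g. eGFR in mL/min/1.73m²,
   potassium in mmol/L) — reported as one family in all acceptance
   statistics, mirroring how the reference deployment's audit counted
   them, but kept as two checkers with two rule schemas.
6. **Teratogens in pregnancy** — gated on the explicit pregnancy flag.
7. **Anticholinergic combinations** — candidate in the group plus at least
   `min_concomitant` distinct active members of the same group.
8. **Suspected hypersensitivity** and 9. **adverse drug reaction
   history** — a recorded target (a cross-reactivity group id or a bare
   ingredient) resolves into the rule's group; suspicion alone fires, as
   unconfirmed records are screened too.

The assembled screen is deduplicated on (rule, conflicting entity) — the
same interaction with two distinct co-prescriptions produces two alerts,
as each names its own conflicting drug — and ordered RED before ORANGE,
then by a fixed family enumeration (regulatory, interactions,
duplications, problem contraindications, clinical variables, teratogens,
geriatrics, anticholinergics, hypersensitivity, ADR), then rule id, then
conflicting entity. The order is total, so any permutation of checker
output yields a byte-identical screen.

## Terminology and matching

ATC codes are normalized to uppercase and validated against the five-level
convention (lengths 1/3/4/5/7, letter/digit pattern). Drug groups match by
include-minus-exclude ATC prefixes at any level — content may target a
whole anatomical group or a single substance — and/or by explicit member
ingredients, which is also the path for combination products. ICD-10
matching is restricted to prefixes at the 3-character category boundary or
longer ("I1" is rejected as a group prefix), and normalized codes carry a
dotted extension, so a prefix "I10" can never accidentally match "I11.0".

## Concomitance, age and measurement semantics

- Prescriptions live on half-open intervals `[start, end)`; "concomitant"
  means active on the prescribing date. Half-open intervals avoid double
  counting at switch dates. An open-ended prescription stays active unless
  its status is "ended".
- Age is completed years under the birthday-anniversary rule; the
  geriatric boundary is exact (alerts at 75, never at 74).
- Clinical-variable rules use the most recent measurement within a
  staleness window (default 365 days — roughly the annual review cycle of
  primary-care chronic disease management). A missing or stale measurement
  silently keeps the rule from firing: an alerting tool should stay quiet
  on absent evidence, not guess.
- Dose-thresholded rules only fire when the prescribed daily dose is known
  and recorded in the rule's unit; the demo thresholds for citalopram
  (> 40 mg/day) and escitalopram (> 20 mg/day) are placeholders, as the
  exact deployed values are not publicly printed.

## Acceptance semantics

An episode records one prescribing decision. All alerts of the episode
share that outcome: *accepted* iff the candidate was **not prescribed**.
`prescribed_modified` (dose reduced or follow-up ordered, drug still
issued) exists precisely so the known undercount of this definition can be
quantified in simulation — it maps to *not accepted*, exactly as the
reference deployment counted. Per-alert differential acceptance is not
representable by design: the tool observes one decision per episode.

Percentages are integer, rounded half away from zero; this reproduces
every percentage cell of the published family-by-year audit summary. One
printed cell in the published geriatric-groups table (the benzodiazepine
row, 47,966/172,574 printed as 27 rather than 28) departs from that
convention; the packaged fixture keeps the printed value and the test
suite documents and excludes that single cell. Published in-text figures
whose denominators are not reconstructible (the "44%" alprazolam share of
benzodiazepine alerts, the "55%" benzodiazepine increase) are not
asserted anywhere.

## The demo rulebase

The packaged content (`demo_rulebase()`) encodes every rule the public
record of the reference deployment names: 14 RED regulatory rules
(Triple Whammy, COXIBs, diclofenac, aceclofenac, cilostazol, ivabradine,
agomelatine, escitalopram, citalopram, trimetazidine,
raloxifene/bazedoxifene, strontium ranelate, aliskiren, canagliflozin),
15 ORANGE geriatric groups, seven duplication groups, the top published
interaction pairs, NSAID and β-lactam cross-reactivity groups, a teratogen
group, an anticholinergic group and two clinical-variable rules. ATC code
assignments are standard reference knowledge supplied by the implementers.
Constraint choices for regulatory rules whose precise conditions are not
public (e.g. the cardiovascular problem groups behind the diclofenac and
COXIB contraindications) are clinically plausible demonstrations, not
clinical content. The rule families are closed: extensibility is via
content tables, never new families, which keeps the engine's contract
auditable.

## The synthetic stream and what passing tests show

`generate_episode_stream()` plants at most one conflict family per
episode, constructing the patient state that guarantees it (e.g. for a
Triple Whammy episode: an ACE inhibitor and a loop/thiazide diuretic
installed, an NSAID candidate; for a geriatric episode: a patient aged
75–94). Defaults are the deployment-scale conditions of the published
audit: one alerting episode per 15 prescriptions, family mix proportional
to the published family totals, per-family acceptance probabilities equal
to the published cumulative rates, a 20% ≥ 75 stratum and a 3% pregnancy
rate among women 18–45. One episode per synthetic patient keeps planted
conflicts independent. Randomness uses two documented substreams: the
population uses `seed`, the episode stream `seed + 1`; identical
configurations are byte-identical.

Because the planted drugs and states are orthogonal under the demo content
(a drug planted for one family triggers no rule of another unless
composed), per-family detection sensitivity and specificity are both
exactly 100% for a correct engine — which is what the validation suite
asserts on a 10,000-episode stream, alongside a 99% binomial-interval
check that observed acceptance matches the configured probability. What
this does **not** show: real prescription streams have correlated
multi-family conflicts, content-dependent false-positive rates, stale
pregnancy flags and unconfirmed hypersensitivity records (both documented
failure modes of the reference deployment), none of which the orthogonal
generator emulates. The simulator validates the engine's mechanics, not
the clinical content.

## Numerical and design choices

- Problem sizes: the validation suite uses 1,000 randomized
  checker-union fixtures, exhaustive 8-subset Triple Whammy enumeration, an
  age 70–80 boundary sweep, 200-case day-iteration concomitance oracles,
  and one 10,000-episode planted stream; these sizes give exact or
  high-power checks while keeping the default run inside a few minutes.
- Ties and ordering: rankings sort descending by generated count with
  label-ascending tie-breaks; screens use the total order above; audit
  logs are returned timestamp-sorted.
- Degenerate inputs: zero-alert episodes are loggable but excluded from
  acceptance statistics (acceptance is undefined, and `is_accepted()`
  errors); `pct()` is undefined at zero generated and renders blank.
- Error policy: rulebase loading reports *all* structural violations at
  once (dangling group references, duplicate rule ids, severity-discipline
  breaches — regulatory rules must be RED, geriatric rules ORANGE);
  evaluation fails fast only on a candidate outside the formulary.
- Whether the deployed system consulted prescription end dates or only an
  active flag is not public; both are representable here (open-ended
  `end_date` plus status).
- Repeat alerts: this engine alerts on every evaluated episode; suppression
  of repeat alerts for an already-alerted ongoing combination is not
  modelled.

## Limitations

The package ships no real ATC/ICD-10 dictionaries and no complete clinical
knowledge base; it does not model dose-interval adjustment, pharmacokinetics,
trimester-specific teratogenicity, free-text mining or prescriber identity.
It is a research artifact for studying rule-based alerting and acceptance
analytics, not a certified clinical tool.
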