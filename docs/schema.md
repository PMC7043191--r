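# Cohort CSV schema

One row per patient, wide layout, UTF-8, header row required.  Missing cells
are empty strings or `NA`.  `itrtree::cohort_schema()` returns this table
programmatically; `read_cohort()` / `write_cohort()` round-trip it.

## Identifier and treatment

| column | type | values / range |
|---|---|---|
| `patient_id` | character | unique |
| `treatment` | factor | `revision_amputation`, `replantation` |

`replantation` is the reference arm: the propensity score is
P(treatment = replantation | X).

## Candidate tailoring covariates

| column | type | values / range |
|---|---|---|
| `age` | numeric | years, >= 18 |
| `n_fingers_amputated` | integer | 1-5 |
| `thumb_amputated` | logical | |
| `dominant_hand_injured` | logical | |
| `mechanism` | factor | `clean_cut`, `avulsion`, `crush` |
| `amputation_level` | factor | `distal`, `proximal` (relative to the PIP/IP joint) |
| `bilateral` | logical | |

The ordinal severity grouping used by sensitivity analysis 1 is derived, not
stored: `derive_injury_group()` maps (`n_fingers_amputated`,
`thumb_amputated`, `amputation_level`) onto levels 1-8.

## Confounders (propensity model only)

`sex` (`male`/`female`), `site` (`US`/`Asia`), `race_ethnicity` (`asian`,
`white`, `black`, `hispanic`, `other`), `education`
(`high_school_or_less`, `some_college`, `college_graduate`), `income`
(`low`/`middle`/`high`), `marital` (`married`/`single`/`other`),
`employment` (`employed`/`unemployed`/`retired`/`other`),
`occupation_group` (`manual`/`non_manual`/`not_working`), `insurance`
(`yes`/`no`), `insurance_type` (`public`/`private`/`none`),
`work_related` (logical).

## Raw bilateral outcome measures

| column | type | range | direction |
|---|---|---|---|
| `grip_injured_kg`, `grip_healthy_kg` | numeric | 0-120 kg | higher better |
| `pinch_lateral_inj_kg`, `pinch_lateral_hea_kg` | numeric | 0-60 kg | higher better |
| `pinch_2pt_inj_kg`, `pinch_2pt_hea_kg` | numeric | 0-60 kg | higher better |
| `pinch_3pt_inj_kg`, `pinch_3pt_hea_kg` | numeric | 0-60 kg | higher better |
| `nine_hole_inj_s`, `nine_hole_hea_s` | numeric | > 0 s | lower better |
| `pain_inj_0_100`, `pain_hea_0_100` | numeric | 0-100 | lower better |
| `mhq_0_100` | numeric | 0-100 | higher better |
| `dash_0_100` | numeric | 0-100 | lower better (reversed as 100 - DASH) |

Composite outcomes are built from these by `composite_outcome()`:
`strength` (mean of four standardized injured-minus-healthy differences),
`dexterity` (standardized healthy-minus-injured peg time), `pain`
(standardized healthy-minus-injured pain, violations truncated), `qol`
(mean of standardized MHQ and standardized reversed DASH).
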