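---
title: "Methods: time-to-event phenotyping of disease progression from multi-source EHRs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-to-event phenotyping of disease progression from multi-source EHRs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Large biobank resources link a baseline assessment to several streams of
routinely collected health data: hospital admission diagnoses and procedures
(ICD-10, OPCS4), death registrations, participant self-report, and — for a
minority of participants — longitudinal primary-care records coded in Read v2
or CTV3. Most phenotyping algorithms collapse this richness into case/control
labels. Studying disease *progression* instead requires, for every
participant, a defensible **event date**, a **censoring date**, and a
**risk-set definition** that removes people who could not have been observed
to progress. `ehrpheno` implements that pipeline end to end, using diabetes
and its vascular complications (a composite cardiovascular outcome, kidney
disease, retinopathy) as the worked phenotype, and ships a synthetic data
generator so the whole machinery is testable without access to restricted
data.

## Codelist curation

Outcome definitions in coded EHRs are lists of clinical codes. The curation
model is: keyword search over a master dictionary (union of Read v2, CTV3 and
TPP-local terminologies), expansion of Read v2 parent codes to all prefix
descendants, forward mapping between Read v2 and CTV3 partner terms,
a usage filter dropping codes never observed in the primary-care extract, and
an annotation file standing in for expert review. Annotations assign each
surviving code one of three roles:

* `DEFINING` — sufficient on its own to classify a participant as a case;
* `DATE_ONLY` — refines the first-incidence date for participants who
  *already* carry a defining code, but never classifies by itself (e.g.
  monitoring and administration codes);
* `EXCLUSION` — removes the participant from the outcome's risk set
  (e.g. kidney disease of clearly non-diabetic aetiology for the kidney
  outcome).

Numerical choices: keyword matching is case-insensitive substring by default
(`regex = TRUE` opts into regular expressions); exclusion keywords take
precedence over inclusion, which is the conservative direction for curation.
The Read v2 hierarchy is the 5-character prefix relation on codes stripped of
trailing `.` padding; CTV3 is *not* prefix-hierarchical, so CTV3 children
must be supplied explicitly. Unannotated candidates default to `DEFINING`
with a warning rather than being silently dropped, so an incomplete
annotation file fails loudly in review rather than quietly in analysis.
Codelists are stored in canonical (C-locale) `(system, code)` order so two
curation runs compare byte-for-byte.

## Event consolidation and first occurrences

All sources are unpivoted into one event-record shape
(`participant, source, system, code, date, valid, reason`). Cleaning never
deletes rows: placeholder dates (the `1900-01-01`-style administrative
sentinels), dates before birth and dates outside a plausibility window set
`valid = FALSE` with a reason tag, preserving the audit trail. Outcome event
tables are role-filtered joins against a codelist; merging across sources
collapses exact `(participant, date, system, code)` duplicates. The first
occurrence per participant is the minimum valid date over `DEFINING` and
(gated) `DATE_ONLY` events; when two sources tie on the minimal date the
reported source label follows a fixed priority
(primary care > hospital > death > self-report > derived fields) — arbitrary
but deterministic, and the date itself is unaffected. Information is taken
directly from hospital/death/primary-care records even when a pre-computed
first-occurrence field exists, because the raw streams are more current.

## Biomarkers

Trajectories combine valued primary-care events (mapped to biomarkers via a
code map) with assessment-centre measurements, harmonised to canonical units
(mmol/L, mmol/mol, mg/mmol, µmol/L, mmHg) by per-unit linear factors;
implausible values are flagged, not dropped. eGFR uses the CKD-EPI 2009
creatinine equation with the race coefficient togglable (the study era
predates the 2021 race-free refit). uACR pairs each urine albumin with the
nearest urine creatinine within 7 days (same-visit panels; ties resolve to
the earlier date). Derived events use explicit stand-in rules where the
source material defers to supplementary detail: microalbuminuria at the first
uACR ≥ 3 mg/mmol and macroalbuminuria at ≥ 30 mg/mmol (the KDIGO A2/A3
thresholds), and prolonged low eGFR as an uninterrupted run below
60 ml/min/1.73m² spanning ≥ 90 days, the event dated at the confirming
measurement. All thresholds are arguments.

Baseline biomarker summaries are computed over the **landmark period** — from
the start of a participant's primary-care record to six months after the
index date — as the mean and coefficient of variation (sd/mean) of valid
in-window measurements. The CV requires at least two measurements (sd is
undefined at n = 1) and a positive mean.

## Cohort construction

The index date (time 0) is the study-initiation date. Follow-up runs to the
earliest of loss-to-follow-up, death and the administrative ("showcase")
cut-off. Diabetes type is assigned from code specificity: only
type-1-specific codes → T1D; only type-2-specific → T2D; both, or only
generic codes → UNCERTAIN (a declared stand-in for the supplementary
multi-rule algorithm; UNCERTAIN participants stay in the cohorts, with type
available as a covariate). Exclusion is flag-based with a fixed reason
precedence so audits are deterministic:

1. event before the first documented evidence of diabetes;
2. event after the censoring date;
3. any risk-set exclusion event on record;
4. events: index not between diabetes evidence and the event date;
5. non-events: diabetes evidence later than 6 months after the index
   (6 months = 182.625 days of calendar arithmetic);
6. outcomes ascertained mainly from primary care (kidney disease,
   retinopathy) require linked primary-care data unless the event is
   documented in hospital/death records;
7. kidney disease only, by default: at least 5 years between diabetes
   evidence and the event, and at least 5 years of risk-set follow-up since
   diabetes evidence (preferentially capturing diabetes-related kidney
   disease); a config switch can extend this to retinopathy;
8. non-positive follow-up (events on the index date are excluded — ties at
   time 0 are not retained).

Weakening any threshold can only grow the retained set (tested as a
property). Incidence rates are events per 1000 person-years with the exact
Poisson (chi-square) confidence interval on the event count.

## Statistical analysis

Missing baseline covariates and biomarker summaries are multiply imputed
(m = 5 by default) by chained equations. Per variable the method is
predictive mean matching — when the variable is categorical, integer-valued,
or skewed (|sample skewness| > 1) — or plain model prediction otherwise;
PMM draws from the k = 5 observed donors with closest predicted means, so
imputed categorical values are always observed levels. The engine is linear
(least-squares) conditionals; the reference implementation used a
random-forest imputer, which we treat as an implementation detail rather
than a contract: what is contracted is the method-choice rule, determinism
given a seed, identical observed cells across panels, and calibration (the
pooled mean of an MCAR variable covers truth at roughly nominal rate, which
the test suite measures by simulation).

Cox models use Efron tie handling. Estimates across imputed panels are
pooled by Rubin's rules (total variance `W̄ + (1 + 1/m)B`, Barnard–Rubin
degrees of freedom); multi-column candidates use the D1 multi-parameter
pooled Wald test. Variable selection is forward-with-backward stepwise where
every add/drop decision uses the pooled p-value (enter/remove at 0.05 by
default), with age and sex forced into every model and never tested. Ties
break on smallest p then alphabetically; the full decision trace is
recorded, and revisiting a model stops the search. Activity (MET), mean uACR
and all CVs are z-scored, using training-set moments only when predicting.

Risk prediction splits participants 2:1 into training and validation (one
split shared by all panels), reselects on the training panels, and scores
each validation participant with the mean over panels of the centred linear
predictor. Discrimination is the Mann–Whitney AUC (ties count ½) against
binary end-of-follow-up status with a DeLong confidence interval — the
censoring-naive reading of an unqualified "AUC"; a time-dependent AUC is out
of scope. Kaplan–Meier curves compare groups split at the median risk score
with a log-rank test.

## The synthetic world

`generate_cohort()` emits the six inputs the pipeline consumes plus a ground
truth table. The stated conditions it encodes: 45% primary-care linkage;
recruitment 2006–2010 at ages ~40–70; hospital records to 2018-02-28 and
primary care to 2017-12-31; complication onsets drawn from
`h(t) = h0·exp(x'β)` with β over age (0.05/year), male sex (0.7), BMI (0.03)
and mean SBP (0.01/mmHg) — magnitudes matching published hazard ratios for
these factors — and baseline rates 16.3/46.2/71.8 per 1000 person-years for
the three complications. Where the stated world is silent we chose once:
diabetes prevalence is enriched to 0.5 (at a realistic ~10% prevalence a
desk-scale run of a few hundred participants would leave too few diabetics
to exercise every exclusion rule); biomarker trajectories are
subject-mean + slope·t + Gaussian noise at Poisson visit times, with
population means at typical diabetic values; 1% of biomarker rows receive
placeholder dates; 15% MCAR missingness on imputable assessment covariates.

Two things the generator deliberately does **not** emulate: correlated
multi-morbidity and code-usage heterogeneity (every event is coded exactly
once, by one code), and informative missingness. A green test therefore
establishes that the pipeline's *logic* is correct — rules, joins, dates,
pooling arithmetic — not that it is robust to real-world coding noise.
Placeholder dates are injected only into biomarker rows so the planted
outcome truth remains authoritative; and derived albuminuria/low-eGFR events
are not fed into the demo cohort path, because threshold crossings of
simulated noise are not part of the planted truth the independent evaluator
predicts. The evaluator (`expected_cohort()`) is a separate, vectorised
transcription of the design rules written against the truth table — it
shares no code with the pipeline, and the suite requires exact agreement on
retained participants, statuses, times and exclusion reasons, plus a
hand-constructed 16-participant fixture with one designed violation per
rule.

## Known limitations

Right censoring only (no interval/left censoring, no competing risks);
no polygenic scores or genetic ancestry (require genotypes); hospital
episodes are treated as dated diagnoses without spell logic; HbA1c unit
conversion beyond a linear rule, SNOMED release parsing and free-text NLP
are out of scope. The fixture keyword lists and annotation files are
illustrative, not authoritative curation content.
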