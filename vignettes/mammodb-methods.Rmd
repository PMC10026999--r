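---
title: "Methods: consolidating screening mammography data for AI validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consolidating screening mammography data for AI validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mammodb)
```

# The problem

Validating a commercial AI-CADe system (computer-aided detection of breast
cancer on screening mammograms) against a screening program requires
consolidating four data components that live in different systems and speak
different formats:

1. **images** — DICOM files exported from a PACS, organized patient /
   study / series / instance;
2. **assessments** — the double-reading decisions recorded per examination
   in a radiology information system (RIS), exported as CSV in a
   non-standard dialect;
3. **cancer outcomes** — diagnosis records from a national quality
   registry, keyed by personal identity number;
4. **inferences** — the AI systems' abnormality scores, delivered in
   per-vendor payload formats.

`mammodb` implements the extract–transform–load layer that joins these
four components in one document store under a consistent pseudonym, plus
the two selection procedures built on top of it: the epidemiological
population definitions (case-control and cohort) and the per-study choice
of which image instances are submitted to each AI system.

Everything is testable offline because the package ships a seeded
synthetic generator for all four inputs.

# Data model

Every stored entity (`ImageMetadata`, `RadiologicalSeries`,
`RadiologicalStudy`, `Patient`, `RISRecord`, `NKBCRecord`,
`InferenceStudyResult`) is a *document*: a nested mapping with store
metadata (data-model version, creation/modification timestamps, project
name for multi-project stores).  Three conventions govern document
bodies:

* *flat is better than nested* — frequently queried fields (study date,
  modality, patient digest) are promoted to the body root; the full DICOM
  tag mapping stays nested below;
* *sparse is better than dense* — a missing value is an absent field,
  never a null placeholder;
* *readability counts* — snake-case field names, uppercase enumerations,
  and DICOM keywords rather than hex tag numbers.

The reference backend is an in-process environment with newline-delimited
JSON import/export, so the full pipeline runs at desk scale without a
database server; the contract (`ds_insert`, `ds_group_by`, ...) is what
the rest of the package programs against, and a server-backed engine
could be substituted behind it.

# Hierarchy construction

Indexing reads only DICOM *headers* — parsing stops at the PixelData
element — and requires each file to be identifiable and placeable:
`SOPInstanceUID` plus either both hierarchy UIDs or the
`(PatientID, StudyDate)` fallback.  Files are found by the literal rule
"any file ending in `.dcm`, at any depth"; valid DICOM under other
extensions is deliberately not probed.

Series group images by `SeriesInstanceUID`; studies group images
*directly* by the unique combination of `PatientID` and `StudyDate` (the
DICOM notion of one patient on one calendar day), with
`StudyInstanceUID` demoted to a union field on the study — a study that
spans two UIDs keeps both.  This follows the aggregation actually used in
screening archives, where one screening visit occasionally produces
multiple study UIDs.

The tags shared by the members of a group are computed by
**intersection-allow-missing-minority** (IAMM): a tag is kept if its
present values all agree *and* it is present in a strict majority of the
member mappings; any disagreement discards the tag.  "Majority" is read
strictly: a tag present in exactly one of two images is discarded, which
avoids fabricating consensus for two-image series.  IAMM is
permutation-invariant and its output is always a subset of the union of
input keys; the test suite checks it against a brute-force per-tag vote
oracle on thousands of random inputs.

Date promotion combines `StudyDate` and `StudyTime` into an ISO 8601
string so calendar arithmetic works downstream.  A missing `StudyTime`
defaults to midnight and fractional seconds are truncated: the
downstream uses (follow-up windows, year strata) operate at day
precision, so sub-second fidelity buys nothing.

# Pseudonymization

The de-identification profile is a modified basic confidentiality
profile:

* nine identifiers (`PatientID`, `AccessionNumber`, `AdmissionID`,
  `InterpretationID`, `PerformedProcedureStepID`,
  `PerformingPhysicianName`, `RequestedProcedureID`, `ResultsID`,
  `StudyID`) are replaced by **salted SHA-512/256** digests instead of
  being blanked, so records remain linkable across sources without being
  reversible by anyone who lacks the salt;
* patient characteristics are binned: day removed from the birth date,
  weight to 5 kg, height to 5 cm (0.05 m on DICOM `PatientSize`), age to
  5 years — nearest bin, halves rounding up (base R `round()` is
  banker's rounding, which would bias bins downward on exact halves);
* acquisition time and study description are preserved; institution
  identity, device identity, and longitudinal temporal information with
  full dates are retained;
* the remaining identifying attributes (patient name, address, phone,
  referring/operating staff names, other patient IDs) fall to the base
  action and are removed.

SHA-512/256 is the truncated-IV variant of FIPS 180-4, implemented in C
in this package because no installed R library provides it; it is pinned
to the published `"abc"` test vector and cross-checked against an
independent reference implementation in the tests.  Two encoding choices
the profile fixes as package constants: digests are lowercase hex, and
the salt is *prepended* (`salt || value`).  The salt never appears in
any document, log, or config file — the CLI takes only the *name* of an
environment variable holding it.

Intended pipeline order: index, pseudonymize, then build the hierarchy,
so grouping keys are already digests and no raw identifier ever reaches
a series/study/patient document.

## Swedish personal numbers

Registry and RIS records are keyed by personnummer, which arrives in
several formats (`19000101-5678`, `190001015678`, `0001015678`) that
would hash to different digests.  Before hashing, a number is cleaned
(all non-alphanumerics deleted) and scored with four independent bits —
alphanumeric (1), correct 12-character length (2), valid `YYMMDD` date
(4), correct Luhn mod-10 checksum over `YYMMDDXXX` (8) — and the score
(0–15) is stored beside the digest so the comparability of two digests
can be asserted later.  Two decisions the scoring scheme leaves open:

* the alphanumeric bit is evaluated *after* cleaning, where it holds for
  any non-empty input; we implement the stated order of operations
  literally rather than guess at intent, and note that the bit carries
  no discriminative power;
* "correct checksum" is implemented as the Luhn mod-10 rule over the
  nine digits of the short form — the only checksum defined for this
  identifier — and isolated behind one function.

Canonicalization maps recoverable inputs to the 12-character form;
10-digit forms get the century that puts the implied age in [0, 100) at
a configurable reference date (default 2021-12-31, the end of the
screening era the generator emulates).  Note the consequence that
`0001015678` canonicalizes to a birth year of 2000, not 1900, at that
reference date.  Uncanonicalizable input is hashed as-cleaned and is
identifiable by its unset date bit.

# Clinical records

**RIS dialect.** Assessment extracts are Windows-1252 encoded with `$`
as column delimiter and `£` as string delimiter.  The reader decodes
each line from Windows-1252 to UTF-8 and splits it with a quote-aware
state machine (`££` inside a quoted span is a literal `£`); undecodable
lines are reported with their byte offset rather than aborting the
load.  The tests check the reader against Python's generic `csv` engine
configured with the same dialect, and against the package's own writer
(write–read identity on random tables).

**Decision collapse.** Each examination carries two independent reads
and one final decision, each one of Discussion / Healthy / Selection /
Technical recall / missing (N/A).  The collapsed *status* of an
examination is the final decision itself: Healthy, Selection and
Technical recall map to themselves, missing stays missing, and
Discussion — which never occurs as a final decision in observed
double-reading data — is a validation error rather than a silent
missing, surfacing upstream data-quality problems.  Status summaries
report counts and percentages rounded half-up to two decimals.  Both
headline counts are exposed: total extracted examinations and the
decided (non-missing) subset.

**Registry outcomes.** Registry rows are parsed against a schema of
typed, enumeration-validated columns (e.g. `a_pat_sida` with codes
`1` → right, `2` → left); values outside an enumeration quarantine the
row with a reason rather than being coerced.  Diagnosis dates are
checked against the configured registry era.  The full original row,
minus the raw personal number, is retained per record for audit.

**Reference standard.** An examination is a cancer case iff a diagnosis
date falls inside `[screening_date, screening_date + w months]`, with
calendar-month addition and end-of-month clamping (adding 36 months to
Jan 31 lands on Jan 31 where it exists, else the month's last day).  A
diagnosis on the screening day counts as within-window, since a
diagnosis that close is the outcome of the screening itself.  The window
`w` is a parameter (default 36 months) precisely because short windows
bias toward radiologist-apparent cancers and long windows add
uncertainty; storing dates rather than labels keeps every alternative
definition available.

# Population selection

**Case-control.** Cases are all women in the outcomes data; each
contributes her exams within 36 months (configurable) *before*
diagnosis.  Controls are sampled from never-diagnosed women with at
least one assessment record, at 5 control participants per case
participant per stratum, stratified by examination year and balanced on
5-year age bins — the bin width mirrors the age binning used at
pseudonymization, since no separate width is canonical.  The ratio
targets *participants* (women), and a selected control contributes all
her exams; this matches selection tables that separate participant and
exam counts.  A stratum with too few eligible controls takes all of them
and flags the shortfall — sampling with replacement is never allowed.
Selection is deterministic under a recorded seed (byte-identical output
files).

**Cohort.** All exams of a calendar year, each labelled case or control
by the reference-standard window; the two arms partition the year's
exams exactly.

Emitted lists come in two dialects: digest-bearing (for verification)
and identifier-bearing (hospital-bound, for retrieving images), the
latter requiring an explicit reversible id-map from a protected side
store.

# AI input selection and inference normalization

Input selection targets the four standard screening views R-MLO, L-MLO,
R-CC, L-CC.  An instance qualifies if its laterality is R/L, its view
position MLO/CC, and its SOP class one of the three accepted storage
classes, ranked in a fixed priority order (the printed priority order is
followed verbatim, including its labelling quirk for the second UID).
Every non-empty qualified set falls into exactly one family:

| occupancy of the four slots            | case  | sets emitted            |
|----------------------------------------|-------|-------------------------|
| all four, singly                       | 1     | one set of 4            |
| all four, some multiply                | 2a/2b | newest / oldest, 4 each |
| some missing, present slots single     | 3     | one set of < 4          |
| some missing, some multiple            | 4a/4b | newest / oldest, < 4    |

"Newest"/"oldest" is resolved per slot independently by acquisition
time, then instance number (the fallback when acquisition time is
absent), then SOP-class rank, then UID lexicographically — the last two
keys exist only to make the choice a deterministic total order.  Both
the 2a and 2b (4a/4b) sets are always produced; which ones a vendor
receives is governed by its capability configuration, not hard-coded.

Vendor dialects are declarative field-path profiles rather than
hard-coded parsers; three ship with the package, mimicking a per-image
JSON shape, a per-laterality JSON shape with an embedded encoded overlay
image, and a DICOM-dataset shape.  Normalization reduces per-image
scores to one score per laterality by the maximum, keeps an absent side
absent, and retains the complete original payload *except* encoded-image
fields, which are stripped recursively before storage.

# The synthetic generator

`generate_world()` draws a deterministic world of women (with valid
personnummer, Luhn check digit included), screening exams spread over
2008–2021, per-exam view-slot occupancies, double-reading decisions, and
registry diagnoses.  Its defaults are the study conditions of the test
suite:

* `decision_mix` — the 28 observed decision combinations with weights
  proportional to their observed counts, so synthetic marginals resemble
  a real program (≈85% healthy, ≈3% selection, ≈0.1% technical recall,
  ≈12% missing);
* `cancer_rate = 0.04` — matching the ≈4% share of ever-diagnosed
  participants in regional screening source populations;
* `duplicate_slot_rate = 0.1`, `missing_slot_rate = 0.1` — no canonical
  values exist; these are set high enough that all six input-selection
  cases occur in small worlds (real archives duplicate and drop views
  far more rarely);
* diagnosis dates are placed 30–1200 days after a random exam of the
  diagnosed woman, straddling the 36-month window so both
  reference-standard outcomes occur.

What the generator does *not* emulate: realistic pixel content (images
carry an 8×8 payload — headers are the object of study), DICOM
conformance beyond what ingestion requires, region-specific RIS column
vocabularies, correlated reader behaviour, or age-dependent cancer
incidence.  Passing tests therefore demonstrate the correctness of the
*mechanics* — parsing, merging, hashing, selection, classification — not
epidemiological realism.

# Problem sizes and numerical choices

The test suite and the reproduction script use: the full 1,296,526-record
expansion for the decision-collapse summary; 1,000 random tag-map lists
(sizes 1–7) for the IAMM oracle; a 50-patient imaging world (~700
images) for hierarchy closure; all 81 slot-occupancy patterns for input
classification; 10,000 random strings for personal-number scoring; and a
2,000–3,000-patient tabular world (~160–250 cases) for population
selection.  These sizes were chosen so every property is exercised well
past its edge cases while the whole suite stays comfortably
interactive.

Other fixed numerical choices, gathered in one place: half-up rounding
for binned characteristics, percentages, and stratum targets; hex
encoding and salt-first concatenation for digests; midnight default and
second-truncation in date promotion; strict majority in IAMM;
`<missing>` as an explicit sentinel group for absent grouping keys
(callers decide, nothing is dropped silently); first-wins
skip-and-report for duplicate `SOPInstanceUID` within a project.

# Known limitations

* Only explicit-VR little-endian DICOM is read; undefined-length
  sequences are rejected (the writer never produces them, and screening
  exports in other transfer syntaxes would need transcoding upstream).
* The in-process store is not a database: no indexing, concurrency, or
  out-of-core aggregation; it is the desk-scale reference backend for a
  contract designed to admit a server-backed engine.
* Multi-day studies and re-grouping by `StudyInstanceUID` are out of
  scope by design; the `(PatientID, StudyDate)` key is authoritative.
* Interval-cancer versus screen-detected sub-classification is not
  modelled; the reference standard is the single-window rule above.
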