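# mammodb

Document-oriented management of mammography screening data for AI
validation.

## What problem this solves

Hospitals that want to evaluate commercial AI-CADe systems (computer-aided
detection of breast cancer on screening mammograms) against their own
screening program must join four data components that live in different
systems: DICOM images from the PACS, double-reading assessments from the
RIS (delivered as CSV in a non-standard dialect: Windows-1252, `$` column
delimiter, `£` string delimiter), diagnosis records from the national
breast-cancer quality registry, and the AI vendors' inference payloads
(two JSON dialects and a DICOM-dataset dialect).  `mammodb` is the
extract–transform–load layer that consolidates all four into one
pseudonymized document store and implements the selection logic built on
top: reference-standard labelling, case-control and cohort population
definitions, and the per-study choice of image instances submitted to
each AI system.

It is aimed at medical-imaging informaticians and screening researchers
building a validation database at their own institution; everything runs
offline at desk scale, and a seeded synthetic generator emulates all four
input sources so the complete pipeline is testable with no patient data.

## The core procedures

**Hierarchy construction.** DICOM headers (pixel data is never read) are
indexed one document per file, then grouped: series by
`SeriesInstanceUID`, studies by the unique combination of
(`PatientID`, `StudyDate`), patients by `PatientID`.  The tags shared by
a group are merged by *intersection-allow-missing-minority*: for a tag
*t* over *n* member mappings,

- keep *t* if all present values agree and *t* is present in a strict
  majority (> *n*/2) of the mappings;
- discard *t* on any disagreement.

**Pseudonymization.** Nine identifiers (patient ID, accession number,
admission ID, interpretation ID, performed-procedure-step ID, performing
physician's name, requested-procedure ID, results ID, study ID) are
replaced by salted SHA-512/256 digests, `hex(SHA-512/256(salt ‖ v))`;
patient characteristics are binned (birth day dropped; weight, height,
age to 5-unit bins, halves up); acquisition time and study description
are preserved; institution identity, device identity and full dates are
retained; other identifying attributes are removed.  Swedish personal
numbers are cleaned, scored with a 4-bit validity mask (alphanumeric = 1,
12-char length = 2, valid `YYMMDD` date = 4, Luhn mod-10 checksum = 8)
and canonicalized to the 12-digit form before hashing, so
`19000101-5678` and `190001015678` produce the same digest.

**Decision collapse.** Each screening examination carries two
independent reads and a final decision in {Discussion, Healthy,
Selection, Technical recall, N/A}.  The collapsed status of an
examination is its final decision (Discussion never occurs as a final
decision and is rejected as a data error).

**Reference standard and populations.** An exam is a cancer case iff a
diagnosis date *d* satisfies `screen ≤ d ≤ screen + w months`
(calendar-month addition, end-of-month clamping; default *w* = 36).
The case-control population takes all diagnosed women (their exams
within 36 months before diagnosis) plus a seeded random sample of
never-diagnosed women with assessments at 5 control participants per
case participant per (examination-year × 5-year-age-bin) stratum; the
cohort population takes all exams of one year labelled by the window.

**AI input selection.** Instances qualify on laterality R/L, view
MLO/CC and an accepted SOP class; a study's qualified set falls into
exactly one input-case family — all four view slots singly occupied
(case 1), all occupied with duplicates (2a newest / 2b oldest per slot),
some slots missing (case 3), missing with duplicates (4a/4b).  Vendor
scores are reduced to one score per laterality by the maximum, and the
original payload is retained minus any embedded encoded images.

## Worked example

```r
library(mammodb)

# Collapse the 28 observed double-reading combinations (1,296,526 exams)
summarize_statuses(expand_decision_mix(default_decision_mix()))
#> # A tibble: 4 × 3
#>   status             count percent
#>   <chr>              <int>   <dbl>
#> 1 HEALTHY          1106090   85.3
#> 2 SELECTION          39320    3.03
#> 3 TECHNICAL_RECALL    1376    0.11
#> 4 NA_DECISION       149740   11.6
```

85.31% of examinations were read healthy, 3.03% recalled for workup,
0.11% technically recalled, 11.55% missing (printed above at tibble
display precision); the decided subset is 1,146,786 of 1,296,526.

```r
# A synthetic world, end to end
world <- generate_world(fixture_config(n_patients = 12, seed = 2025))
world
#> <fixture_world> seed 2025 : 12 patients, 30 exams, 120 images, 0 diagnoses

emit_dicom_tree(world, "tree")
store <- doc_store()
ingest_images(store, scan_dicom_tree("tree"), "demo")
#> <ingest_report> ok: 120  failed: 0  skipped: 0
deidentify_project(store, "demo", deid_profile("demo-salt"))
build_hierarchy(store, "demo")$studies
#> <build_report> created: 30  skipped: 0  missing-key images: 0

sid <- ds_ids(store, "RadiologicalStudy")[2]
classify_input_case(qualify_instances(store, sid)$qualified)$cases
#> [1] "CASE_3"
ds_get(store, "RadiologicalStudy", sid)$body$patient_pseudo_id
#> [1] "1093474f72380f77424d7cdd5340b18a3f4f7b055d0de22615bfdf8375835900"
```

The 120 synthetic files ingest cleanly, group into 30 studies keyed by
the salted patient digest, and this particular study is missing at least
one view slot, so it classifies as input case 3 (one input set with
fewer than four instances).

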