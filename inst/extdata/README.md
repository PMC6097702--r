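# External data

The package ships no subject-level data; everything in the test suite is
generated in code by the synthetic-data module.

The checks in `tests/testthat/test-acceptance.R` that reproduce the numbers
published for the original lesion cohort look here for CSV exports of the
study's deposited supplementary spreadsheets. To run them, export the
deposited sheets to CSV (long or wide layout; see `?read_expression` and
`?read_behavior` for the accepted headers) and place them in this directory
before installing:

- `s2_expression.csv` — pCREB-positive nuclei density by subject, group and
  brain region (control and lesioned groups)
- `s1_behavior.csv` — total freezing time by subject and group,
  conditioning cohort
- `s4_behavior.csv` — total freezing time by subject and group,
  double-lesion cohort

Without these files the corresponding checks report failures stating that
the deposited data are unavailable; all other checks are self-contained.
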