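# External data slot

Place the archival coding sheet of the comparative artificial-grammar-learning
meta-analysis here as `archival_coding_sheet.csv` to let the acceptance tests
compare this package's fits against the published results. The sheet is not
redistributed with the package.

Expected layout (precomputed-effects format, auto-detected by
`read_coding_sheet()`): one row per effect with columns

- `article_id`, `study_id` — the nesting identifiers
- `g`, `v_g` — Hedges' g and its sampling variance
- `n` — total participants for the effect
- moderator columns: `animal_species`, `animal_class`
  (`human_adult` / `human_child` / `nonhuman_mammal` / `bird`),
  `human_vs_nonhuman`, `stimulus_modality`, `test_response`, `test_type`,
  `log_training_length`, `categories_in_language`, `vocabulary_size`,
  `repetition_of_items`, `adjacent_dependencies`, `nonadjacent_dependencies`
  (binary moderators coded `present` / `absent`)

A raw long-format sheet (per-session summary statistics, see the package
vignette) is accepted as well; it is harmonized at ingest.

Synthetic sheets with this exact schema are produced by
`simulate_raw_studies()` / `write_coding_sheet()` and by
`analysis/01_simulate.R`.
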