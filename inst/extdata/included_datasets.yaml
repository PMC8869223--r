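# The ten liver-transcriptome comparisons of the five public GEO series this
# toolkit was designed around (series accessions are real; the per-sample
# identifiers below are SYNTHETIC placeholders -- group sizes, sex, age and
# diet codes mirror the published study table; actual GSM ids would be
# substituted when the matrices are downloaded).
#
# Diet coding: first letter mother's diet, second the offspring's
# (C control, O obesogenic). `group_label_printed` preserves the group label
# as printed in the source table even where it disagrees with the comparison
# id (GSE134976_CCvsOC and GSE44901 rows); the diet_code fields follow the
# comparison id.
comparisons:
- comparison_id: GSE123009_12w
  study_id: GSE123009
  offspring_sex: M
  offspring_age_weeks: 12
  diet_code_a: CO
  diet_code_b: OO
  group_label_printed: CO vs. OO
  group_a_samples: [GSE123009_12w_a1, GSE123009_12w_a2, GSE123009_12w_a3, GSE123009_12w_a4, GSE123009_12w_a5, GSE123009_12w_a6, GSE123009_12w_a7]
  group_b_samples: [GSE123009_12w_b1, GSE123009_12w_b2, GSE123009_12w_b3, GSE123009_12w_b4, GSE123009_12w_b5, GSE123009_12w_b6, GSE123009_12w_b7]
- comparison_id: GSE123009_28w
  study_id: GSE123009
  offspring_sex: M
  offspring_age_weeks: 28
  diet_code_a: CO
  diet_code_b: OO
  group_label_printed: CO vs. OO
  group_a_samples: [GSE123009_28w_a1, GSE123009_28w_a2, GSE123009_28w_a3, GSE123009_28w_a4, GSE123009_28w_a5, GSE123009_28w_a6, GSE123009_28w_a7, GSE123009_28w_a8, GSE123009_28w_a9]
  group_b_samples: [GSE123009_28w_b1, GSE123009_28w_b2, GSE123009_28w_b3, GSE123009_28w_b4, GSE123009_28w_b5, GSE123009_28w_b6, GSE123009_28w_b7, GSE123009_28w_b8, GSE123009_28w_b9]
- comparison_id: GSE134976_COvsOO
  study_id: GSE134976
  offspring_age_weeks: 12
  diet_code_a: CO
  diet_code_b: OO
  group_label_printed: CO vs. OO
  group_a_samples: [GSE134976_COvsOO_a1, GSE134976_COvsOO_a2, GSE134976_COvsOO_a3]
  group_b_samples: [GSE134976_COvsOO_b1, GSE134976_COvsOO_b2, GSE134976_COvsOO_b3]
- comparison_id: GSE134976_CCvsOC
  study_id: GSE134976
  offspring_age_weeks: 12
  diet_code_a: CC
  diet_code_b: OC
  group_label_printed: CO vs. OO
  group_a_samples: [GSE134976_CCvsOC_a1, GSE134976_CCvsOC_a2, GSE134976_CCvsOC_a3]
  group_b_samples: [GSE134976_CCvsOC_b1, GSE134976_CCvsOC_b2, GSE134976_CCvsOC_b3]
- comparison_id: GSE40903_COvsOO
  study_id: GSE40903
  offspring_sex: M
  offspring_age_weeks: 9
  diet_code_a: CO
  diet_code_b: OO
  group_label_printed: CO vs. OO
  group_a_samples: [GSE40903_COvsOO_a1, GSE40903_COvsOO_a2, GSE40903_COvsOO_a3, GSE40903_COvsOO_a4, GSE40903_COvsOO_a5, GSE40903_COvsOO_a6, GSE40903_COvsOO_a7, GSE40903_COvsOO_a8, GSE40903_COvsOO_a9]
  group_b_samples: [GSE40903_COvsOO_b1, GSE40903_COvsOO_b2, GSE40903_COvsOO_b3, GSE40903_COvsOO_b4, GSE40903_COvsOO_b5, GSE40903_COvsOO_b6, GSE40903_COvsOO_b7, GSE40903_COvsOO_b8, GSE40903_COvsOO_b9]
- comparison_id: GSE40903_CCvsOC
  study_id: GSE40903
  offspring_sex: M
  offspring_age_weeks: 9
  diet_code_a: CC
  diet_code_b: OC
  group_label_printed: CC vs. OC
  group_a_samples: [GSE40903_CCvsOC_a1, GSE40903_CCvsOC_a2, GSE40903_CCvsOC_a3, GSE40903_CCvsOC_a4, GSE40903_CCvsOC_a5, GSE40903_CCvsOC_a6, GSE40903_CCvsOC_a7, GSE40903_CCvsOC_a8, GSE40903_CCvsOC_a9]
  group_b_samples: [GSE40903_CCvsOC_b1, GSE40903_CCvsOC_b2, GSE40903_CCvsOC_b3, GSE40903_CCvsOC_b4, GSE40903_CCvsOC_b5, GSE40903_CCvsOC_b6, GSE40903_CCvsOC_b7, GSE40903_CCvsOC_b8, GSE40903_CCvsOC_b9]
- comparison_id: GSE44901_CCvsOC
  study_id: GSE44901
  offspring_sex: M
  offspring_age_weeks: 29
  diet_code_a: CC
  diet_code_b: OC
  group_label_printed: CO vs. OO
  group_a_samples: [GSE44901_CCvsOC_a1, GSE44901_CCvsOC_a2, GSE44901_CCvsOC_a3, GSE44901_CCvsOC_a4, GSE44901_CCvsOC_a5]
  group_b_samples: [GSE44901_CCvsOC_b1, GSE44901_CCvsOC_b2, GSE44901_CCvsOC_b3, GSE44901_CCvsOC_b4, GSE44901_CCvsOC_b5]
- comparison_id: GSE44901_OCvsOO
  study_id: GSE44901
  offspring_sex: M
  offspring_age_weeks: 29
  diet_code_a: OC
  diet_code_b: OO
  group_label_printed: CC vs. OC
  group_a_samples: [GSE44901_OCvsOO_a1, GSE44901_OCvsOO_a2, GSE44901_OCvsOO_a3, GSE44901_OCvsOO_a4, GSE44901_OCvsOO_a5]
  group_b_samples: [GSE44901_OCvsOO_b1, GSE44901_OCvsOO_b2, GSE44901_OCvsOO_b3, GSE44901_OCvsOO_b4, GSE44901_OCvsOO_b5]
- comparison_id: GSE46359_F
  study_id: GSE46359
  offspring_sex: F
  offspring_age_weeks: 2
  diet_code_a: CC
  diet_code_b: OC
  group_label_printed: CC vs. OC
  group_a_samples: [GSE46359_F_a1, GSE46359_F_a2, GSE46359_F_a3, GSE46359_F_a4, GSE46359_F_a5, GSE46359_F_a6]
  group_b_samples: [GSE46359_F_b1, GSE46359_F_b2, GSE46359_F_b3, GSE46359_F_b4, GSE46359_F_b5, GSE46359_F_b6]
- comparison_id: GSE46359_M
  study_id: GSE46359
  offspring_sex: M
  offspring_age_weeks: 2
  diet_code_a: CC
  diet_code_b: OC
  group_label_printed: CC vs. OC
  group_a_samples: [GSE46359_M_a1, GSE46359_M_a2, GSE46359_M_a3, GSE46359_M_a4, GSE46359_M_a5, GSE46359_M_a6]
  group_b_samples: [GSE46359_M_b1, GSE46359_M_b2, GSE46359_M_b3, GSE46359_M_b4, GSE46359_M_b5, GSE46359_M_b6]
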