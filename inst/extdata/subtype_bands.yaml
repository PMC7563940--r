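# Subtype-band registry: five ER/PR/HER2/Ki-67 groups ordered fastest first.
# TVDT ranges are closed intervals on integer days and partition [10, 270].
# mean_tvdt_mts_range entries are display values for rendered tables only;
# no computation uses them. tvdt_pt_display_range mirrors the conventional
# tabulated primary-tumor range where it differs from the model range.
bands:
  - band_id: V
    label: "Triple-negative"
    receptor_rule: "HR(-)/HER2(-), Ki-67 >= 14%"
    growth_class: "rapid"
    tvdt_pt_range: [10, 135]
    tvdt_pt_display_range: [80, 135]
    tvdt_pt_mean: 110
    tvdt_mts_range: [10, 135]
    mean_tvdt_mts_range: [40, 67]
    prognosis_table_label: "Poor"
    prognosis_app_label: "unfavorable"
    screening_interval_months: 3
    screening_interval_months_narrative: 3
  - band_id: IV
    label: "HER2-positive"
    receptor_rule: "HR(-)/HER2(+), Ki-67 >= 14%"
    growth_class: "intermediate"
    tvdt_pt_range: [136, 165]
    tvdt_pt_mean: 150
    tvdt_mts_range: [136, 165]
    mean_tvdt_mts_range: [68, 82]
    prognosis_table_label: "Intermediate"
    prognosis_app_label: "mid-favorable"
    screening_interval_months: 5
    screening_interval_months_narrative: 5
  - band_id: III
    label: "Luminal B (HER2-negative)"
    receptor_rule: "HR(+)/HER2(-), Ki-67 >= 14%"
    growth_class: "intermediate"
    tvdt_pt_range: [166, 195]
    tvdt_pt_mean: 180
    tvdt_mts_range: [166, 195]
    mean_tvdt_mts_range: [83, 97]
    prognosis_table_label: "Intermediate"
    prognosis_app_label: "mid-favorable"
    screening_interval_months: 6
    screening_interval_months_narrative: 6
  - band_id: II
    label: "Luminal B (HER2-positive)"
    receptor_rule: "HR(+)/HER2(+), Ki-67 >= 14%"
    growth_class: "slow"
    tvdt_pt_range: [196, 230]
    tvdt_pt_mean: 210
    tvdt_mts_range: [196, 230]
    mean_tvdt_mts_range: [98, 115]
    prognosis_table_label: "Intermediate"
    prognosis_app_label: "mid-favorable"
    screening_interval_months: 8
    screening_interval_months_narrative: 8
  - band_id: I
    label: "Luminal A"
    receptor_rule: "HR(+)/HER2(-), Ki-67 < 14%"
    growth_class: "very slow"
    tvdt_pt_range: [231, 270]
    tvdt_pt_mean: 250
    tvdt_mts_range: [231, 270]
    mean_tvdt_mts_range: [116, 135]
    prognosis_table_label: "Good"
    prognosis_app_label: "favorable"
    screening_interval_months: 12
    screening_interval_months_narrative: 9

# Column structure: for a primary tumor of each subtype, the metastasis bands
# that appear in its diagnostic column (fastest first) and the TVDT at which
# the late-seeding "(+)" extension is evaluated (none for subtype I).
columns:
  V:
    mts_bands: [V]
    plus_at: 135
  IV:
    mts_bands: [V, IV]
    plus_at: 165
  III:
    mts_bands: [V, IV, III]
    plus_at: 195
  II:
    mts_bands: [V, IV, III, II]
    plus_at: 230
  I:
    mts_bands: [V, IV, III, II, I]
    plus_at: ~
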