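characteristics:
- name: sample_size
  type: quantitative
- name: study_duration_weeks
  type: quantitative
- name: fev1_inclusion_pct
  type: quantitative
- name: fvc_inclusion_pct
  type: quantitative
- name: smoking_pack_years
  type: quantitative
- name: quality_score
  type: quantitative
- name: fev1_min_pct
  type: quantitative
  summary_group: fev1_mean_range
- name: fev1_max_pct
  type: quantitative
  summary_group: fev1_mean_range
- name: allocation_concealment
  type: binary
  levels:
  - inadequate
  - adequate
- name: double_blinding
  type: binary
  levels:
  - 'no'
  - 'yes'
- name: withdrawal_description
  type: binary
  levels:
  - 'no'
  - 'yes'
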