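characteristics:
- name: sample_size
  type: quantitative
- name: study_duration_months
  type: quantitative
- name: disease_duration_years
  type: quantitative
- name: mtx_use
  type: binary
  levels:
  - 'no'
  - 'yes'
- name: ra_duration
  type: ordinal
  levels:
  - early
  - established
  - late
- name: anti_tnf
  type: binary
  levels:
  - 'no'
  - 'yes'
- name: prior_drugs_failed
  type: nominal
  levels:
  - DMARDs
  - biologic
  - both
- name: prior_tnf_failure
  type: binary
  levels:
  - 'no'
  - 'yes'
- name: biologic_combination
  type: binary
  levels:
  - 'no'
  - 'yes'
- name: naive_biologic
  type: binary
  levels:
  - 'no'
  - 'yes'
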