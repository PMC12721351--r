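# Acuity-circle implementation dates per organ and the study end date.
implementation:
  lung: 2017-11-24
  heart: 2018-10-18
  liver: 2020-02-04
  kidney: 2021-03-15
study_end: 2023-11-30
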