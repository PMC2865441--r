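# Illustrative ocular-hypertension population summary (NOT the published
# trial statistics, which are not reproduced here): truncated-normal
# marginals per continuous risk factor, Bernoulli diabetes, categorical
# gender. Bounds emulate eligibility truncation.
n_cases: 50
seed: 20100408
continuous:
  age: {mean: 55, sd: 9.5, lower: 40, upper: 80}
  iop: {mean: 24.9, sd: 2.7, lower: 22, upper: 32}
  cdr: {mean: 0.39, sd: 0.19, lower: 0.0, upper: 0.8}
  psd: {mean: 1.91, sd: 0.2, lower: 0.5, upper: 3.0}
  cct: {mean: 573, sd: 38, lower: 450, upper: 700}
binary:
  diabetes: 0.12
categorical:
  gender: {female: 0.43, male: 0.57}
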