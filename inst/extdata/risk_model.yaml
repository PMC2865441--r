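# Illustrative 5-year risk model (weighted sum of risk factors through a
# logistic link). Coefficients are NOT the published calculator's; they
# are tuned only so that the simulated risk distribution is right-skewed
# with mean near 0.14.
link: logistic
intercept: -2.76
risk_horizon: 5
coefficients:
  age: 0.02
  iop: 0.08
  cdr: 1.5
  psd: 0.3
  cct: -0.006
  diabetes: -0.2
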