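# Demo pipeline: 50 cases reviewed by 50 simulated physicians.
seed: 20100408
risk_unit: proportion
population: population.yaml
risk_model: risk_model.yaml
panel: panel.yaml
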