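# Demo configuration for the synthetic end-to-end workflow:
# simulate -> PAS -> screens -> pharm. All parameters omitted here fall
# back to default_pipeline_config().
seed: 1
alpha: 0.05
r_min: 0.2
log_base: 10
eps: 1.0e-8
regulation_threshold: 0.2
pathway_effect:
  activated: PW01
  delta: 1
  n_case: 3
  n_ctrl: 3
  sigma: 0.05
screen_n_samples: 80
pharm:
  n_lines: 40
  noise_ratio: 0.5
  slope: 1
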