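# Example configuration for the flexreach CLI.
# Unset fields fall back to the package defaults (see flexreach_config()).
seed: 1
task:
  kind: delayed
  n_steps: 300
  delay: 100
  repetitions: 10
precisions:
  alpha: 0.5
  lambda: 0.5
visual_model:
  type: analytic
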