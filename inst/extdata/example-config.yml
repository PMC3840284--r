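# Example aeforage experiment configuration.
# Omitted keys take the documented defaults (standard 60-trial sessions,
# 0.001 J titration step, 3-s ITI, minimum 18 sessions per condition).
seed: 42
ae_start: 0.010
conditions: [15, 30, 60, 30, 15]
output_dir: logs
schedule:
  ae_step: 0.001
  iti: 3
  reinforcer_duration: 4
agent:
  preset: stationary
  tau: 0.005
  a_star:
    "15": 0.02
    "30": 0.04
    "60": 0.08
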