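# One-parameter, one-metric worked example: metric 1 - x^2 with Gaussian
# noise (sd 0.05), target band [0.6, 0.68], ternary search.
parameters:
  x:
    domain: [-1.0, 1.0]
metrics:
  metric1:
    target: [0.6, 0.68]
dependencies:
  x: [metric1]
m:
  "1": 3
max_depth: 5
replicates: 100
max_processes: 1
seed: 1
evaluator:
  type: synthetic
  landscape: fig6a
  noise_sd: 0.05
output: stopt-fig6a
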