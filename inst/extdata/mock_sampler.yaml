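# End-to-end external-evaluator demo: tune a random-walk MCMC move size so
# the proposal acceptance rate lands in [0.3, 0.6].  The executable path is
# resolved by the CLI / run_config caller; "Rscript" plus the bundled
# mock_sampler.R script.
parameters:
  move_size:
    domain: [0.1, 20.0]
metrics:
  acceptance:
    target: [0.3, 0.6]
dependencies:
  move_size: [acceptance]
m:
  "1": 4
max_depth: 4
replicates: 2
max_processes: 1
seed: 1
evaluator:
  type: external
  executable: Rscript
  args: [mock_sampler.R]   # replaced with the installed path by the CLI
output: stopt-mock-sampler
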