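# Demo run: synthetic staircase heart rate tracked by the nearest-neighbor
# neural state machine. Execute with
#   run_experiment(system.file("extdata", "demo_config.yaml", package = "hrsnn"),
#                  out_dir = "demo_out")
duration: 60.0
fs: 125.0
hr:
  from: 65.0
  to: 145.0
  n_steps: 4
arch: nnnsm
bands: wide
order: 2
gain: 8
seed: 11
mismatch_cv: 0.2
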