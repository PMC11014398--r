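# Miniature end-to-end run: small pools, 200 clips, width-scaled models,
# 2 training epochs, 2 repeated runs per distillation method.
seed: 3
outdir: ecodistill_smoke
fixtures:
  speech: 8
  background: 8
  bird: 4
  soundscape: 2
  n_classes: 8
  soundscape_duration_s: 30
dataset:
  n_total: 200
model:
  width_mult: 0.0625
distill:
  max_epochs: 2
  batch_size: 16
  students: [4]
evaluate:
  runs: 2
  bootstrap_B: 200
playback:
  n_per_cell: 2
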