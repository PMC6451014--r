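format: auto
gap_policy: pairwise_deletion
groups: ~
k: 3.0
model: dayhoff_ml
outdir: protspace_run
overlay: centroid
restarts: 10.0
seed: 1.0
tree: nj
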