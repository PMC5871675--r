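# Example run configuration: a pilot-scale sparse organ.
# Usage:
#   inst/cli/proportionator simulate --config example-config.yaml --out run/
#   inst/cli/proportionator sample   --config example-config.yaml \
#       --tiles run/tiles.csv --out run/sample.json
#   inst/cli/proportionator count    --tiles run/tiles.csv \
#       --sample run/sample.json --out run/counts.csv
#   inst/cli/proportionator estimate --config example-config.yaml \
#       --tiles run/tiles.csv --counts run/counts.csv --out run/estimate.json
organ:
  height_um: 1080        # organ height perpendicular to sectioning
  width_um: 2200         # rectangular cross section, A = width * depth
  depth_um: 2200
  n_cells: 210           # ground-truth total (sparse)
  nucleus_diameter_um: 8
  endplate_weight: 0.7   # fraction of cluster parents in the end zones
  seed: 5
stain:
  pixels_per_cell_mean: 20
  background_rate: 0.05  # expected nonspecific pixels per tile
  artifact_rate: 0       # probability of a stain-trapping blob per tile
  false_negative_rate: 0
design:
  thickness_um: 6        # section (= disector) thickness
  n_pairs: 15            # target number of section pairs
  frame_um: 200          # unbiased sampling frame side
  n_tiles: 22            # tiles per independent sampling
  repetitions: 3
  tile_fraction: 1
  units_per_animal: 1
  policy: exclude_rescale
seeds:
  simulate: 9
  sample: 10
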