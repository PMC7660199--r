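# Example simulation configuration: a small two-channel, four-cycle run.
# Keys mirror the sim_config() arguments; n_cycles and n_channels are
# required, everything else falls back to the package defaults.
image_size: [192, 192]
n_cycles: 4
n_channels: 2
n_cells: 3
cell_radius: 30
spots_per_cell_per_target: 6
nonspecific_rate: 2
drift_per_cycle: [0.5, -0.3]
seed: 11
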