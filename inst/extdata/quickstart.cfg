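# egressr quickstart campaign: three egress channels, small replica count.
# Any key omitted here falls back to the package default (see
# ?campaign_config); units are kcal/mol, Angstrom, K, ps.
n_channels = 3
barriers = 4, 6, 10
landscape_seed = 1
n_replicas = 12
base_seed = 1
scale = 0.6
rpp_k = 0.024
cleanup_threshold = 3
cluster_threshold = 3
n_frames = 10
metad_steps = 100000
fep_samples = 100
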