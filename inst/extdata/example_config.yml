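# Example pipeline configuration: surrogate-backed screening of the radial
# model, reduced mesh, deterministic seed. All study_config() fields are
# accepted as top-level keys; omitted keys take the package defaults
# (baseline geometry and factor levels).
out_dir: results/example
orientations: radial
mode: surrogate
mesh_level: coarse
seed: 42
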