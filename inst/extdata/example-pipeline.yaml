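# Example pipeline configuration. Every key is optional; the values shown
# are the defaults. `tracers: default` runs the built-in synthetic tracer
# suite; replace it with a list of template rows to define custom studies.
seed: 1
n_boot: 10000
alpha: 0.05
policy:
  percentile_cut: 5        # bottom-percentile component of the filter (%)
  absolute_threshold: 0.1  # binding-unit component of the filter
  combine: and             # and | or | percentile_only
atlas:
  n_cortex: 100
  n_subcortex: 54
consistency:
  n_replicates: 1
  mode: original_vs_others # or all_pairs
tracers: default
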