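# Modified Asthma Predictive Index (mAPI) rule configuration, version 1.
# The index is positive when the child had at least `min_wheeze_episodes`
# wheeze episodes in the past year AND meets at least `min_major` major
# criterion or at least `min_minor` minor criteria. Kept as configuration
# rather than code so alternative published variants can be swapped in.
version: 1
min_wheeze_episodes: 4
min_major: 1
min_minor: 2
major_criteria:
  - parental_asthma
  - eczema_dx
  - aeroallergen_sensitized
minor_criteria:
  - food_sensitized
  - wheeze_apart_from_colds
  - eosinophils_ge_4pct
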