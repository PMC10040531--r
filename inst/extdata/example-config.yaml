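# Example experiment overrides for the laawash CLI (--config).
n_subjects: 4
washout_horizon: 200
co_levels: [3.3, 4.4, 5.5]
hct_levels: [0.274, 0.455, 0.604]
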