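# two-bottle choice: 10% v/v ethanol vs water, 12:12 with lights off at 0800 h
lights_off=8
dark_hours=12
min_licks_per_bout=20
bout_gap_s=10
lick_bin_edges=20,45,70,95,120,145,170,195
pump_uL_per_step=1
steps_per_lick=5
pump_noise_cv=0.15
experiment_start=2024-03-01T20:00:00
retry_mean_s=30
max_retries=3
fluid.E.label=etoh10
fluid.E.ethanol_fraction=0.1
fluid.E.density=0.789
fluid.W.label=water
fluid.W.ethanol_fraction=0
fluid.W.density=0.789
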