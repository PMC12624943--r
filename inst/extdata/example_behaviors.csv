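subject_id,bout_rate_dark,bout_rate_light,ethanol_choice_p,lick_count_logmean,lick_count_logsd,interlick_mean_s,interlick_shape
rat1,5,1.25,0.85,4.2485,0.6,0.15,20
rat2,6,1.5,0.75,4.2485,0.6,0.15,20
rat3,4.5,1.125,0.7,4.2485,0.6,0.15,20
rat4,5.5,1.375,0.5,4.2485,0.6,0.15,20
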