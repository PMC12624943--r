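subject_id,rfid,body_mass_g
rat1,RF000101,295
rat2,RF000102,310
rat3,RF000103,288
rat4,RF000104,305
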