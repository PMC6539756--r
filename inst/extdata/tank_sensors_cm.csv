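# water-tank 12-position receiver geometry, units = cm, ref_index = 1
x,y,z
70.5,53.0,31.0
70.5,40.5,31.0
56.5,40.5,31.0
42.5,40.5,31.0
42.5,53.0,31.0
42.5,65.0,31.0
56.5,65.0,31.0
70.5,65.0,31.0
70.5,65.0,43.0
70.5,40.5,43.0
42.5,40.5,43.0
42.5,65.0,43.0
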