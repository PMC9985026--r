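timestamp_s,red,ir
0.000,131000,135000
0.020,131150,135400
0.040,130980,134890
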