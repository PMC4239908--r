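t,x,y,z
0.000000000,0.000000000,0.000000000,10.000000000
0.050000000,0.750000000,0.100000000,9.900000000
0.100000000,1.500000000,0.200000000,9.800000000
0.150000000,2.250000000,0.300000000,9.700000000
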