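technique,lo,hi
raman,977,1049
raman,1231,1325
raman,1562,1709
raman,2785,2899
nir,4004,4100
nir,5222,5307
nmr,3.43,5.00
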