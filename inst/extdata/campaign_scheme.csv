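campaign,collected_samples,sampling_points,heavy_metals,pah,hc
C1,83,24,11,11,2
C2,103,37,11,11,2
C3,27,10,11,11,2
C4,22,10,11,15,2
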