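method,NM,BG,CL
GSI-Lines,73.0,67.2,52.8
GSI-Joints,74.8,68.9,54.1
GEI,96.9,85.4,71.2
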