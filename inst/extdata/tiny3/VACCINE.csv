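VAERS_ID,VAX_TYPE
R1,DTAP
R1,MMR
R2,FLU
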