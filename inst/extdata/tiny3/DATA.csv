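VAERS_ID,RECVDATE,SEX,AGE_YRS
R1,07/02/1991,F,1
R2,07/02/1991,F,30
R3,03/15/1992,M,
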