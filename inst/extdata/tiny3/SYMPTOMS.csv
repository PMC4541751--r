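VAERS_ID,SYMPTOM
R1,Fever
R1,Fever
R2,Rash
R2,Fever
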