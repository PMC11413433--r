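icd_code,long_title
R07.9,"Chest pain, unspecified"
D64.9,"Anemia, unspecified"
G43.0,Migraine without aura
S02.1,Fracture of base of skull
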