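{"doc_id":"ex-1","text":"patient admitted with chest pain and anemia","labels":["R07.9","D64.9"],"split":"train"}
{"doc_id":"ex-2","text":"migraine without aura reported for 3 days","labels":["G43.0"],"split":"train"}
{"doc_id":"ex-3","text":"follow up after orbital fracture","labels":["S02.1"],"split":"dev"}
{"doc_id":"ex-4","text":"anemia follow up with fatigue","labels":["D64.9"],"split":"test"}
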