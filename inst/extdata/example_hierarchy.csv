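node_id,parent_id,level
G43.0,G43,leaf
G43.1,G43,leaf
G43,G40-G47,family
G40-G47,,block
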