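protein_id,chain_a,pos_a,chain_b,pos_b
insulin,1,6,1,11
insulin,1,7,2,7
insulin,1,20,2,19
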