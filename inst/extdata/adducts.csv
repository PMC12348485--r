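label,polarity,atoms_added,atoms_removed,charge
[M+H]+,positive,H,,1
[M+Na]+,positive,Na,,1
[M+K]+,positive,K,,1
[M-H]-,negative,,H,-1
[M+Cl]-,negative,Cl,,-1
[M+HCOO]-,negative,CHO2,,-1
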