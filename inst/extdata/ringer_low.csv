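# low-NaCl (apical dilution) Ringer's: 70 mM NaCl, gluconate salts as in high
# osmolarity restored with mannitol (neutral, omitted)
species,charge,mM,alpha_nm
Na,1,70,0.4
Cl,-1,70,0.3
Ca,2,1.2,0.6
Mg,2,1.1,0.8
gluconate,-1,4.6,0.45
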