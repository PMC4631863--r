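ligand_id,e_binding_kcal_mol,ki_uM
Betulin,-6.66,13.12
Betulinic acid,-5.62,75.66
Bisdemethoxycurcumin,-5.92,45.86
Curcumin,-4.89,260.62
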