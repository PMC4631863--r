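ligand_id,substrate_id,target_id,K1_uM,Ka_uM,K4_uM,Kb_direct_uM,reported_kb_pred_uM,reported_mode
Betulin,Maltose,Rattus alpha-amylase model,427180,13.66,938020,23.36,29.99,noncompetitive
Betulinic acid,Maltose,Porcine pancreatic alpha-amylase,493240,75.66,942460,149.13,144.26,noncompetitive
Bisdemethoxycurcumin,Maltose,Human alpha-amylase,791530,45.86,682600,83.49,39.55,competitive_or_uncompetitive
Curcumin,Maltose,Human alpha-amylase,791530,260.62,132.63,841.04,0.044,competitive_or_uncompetitive
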