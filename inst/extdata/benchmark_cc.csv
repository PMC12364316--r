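system,ligand,class,ligand_cc_pred,ligand_cc_fitted,ligand_cc_gt,pocket_cc_pred,pocket_cc_fitted,pocket_cc_gt,protein_cc_pred,protein_cc_fitted,protein_cc_gt,plie_pred,plie_fitted,needed_refinement
LRRK2,MLi-2,kinase,0.8,0.8,0.9,0.7,0.7,0.73,0.46,0.55,0.63,-7.3,-8.2,FALSE
PI3Ka,Alpelisib,kinase,0.7,0.7,0.75,0.55,0.6,0.65,0.45,0.52,0.56,-8.9,-7.4,FALSE
H1R,Desloratadine,GPCR,0.64,0.62,0.68,0.52,0.55,0.71,0.52,0.54,0.7,-11.7,-7.3,FALSE
HCA3,Acifran,GPCR,0.35,0.61,0.76,0.52,0.6,0.71,0.54,0.53,0.67,-8.9,-6.6,TRUE
GlyT1,SSR504734,transporter,0.24,0.62,0.67,0.68,0.78,0.82,0.58,0.7,0.71,-6.4,-7.9,TRUE
CHT1,Hemicholinium-3,transporter,0.2,0.7,0.8,0.43,0.64,0.8,0.53,0.61,0.67,-12.6,-10.1,TRUE
ThTr2,Thiamine,transporter,0.4,0.7,0.8,0.5,0.7,0.72,0.51,0.74,0.8,-15.8,-20.1,TRUE
NET,Bupropion,transporter,0.35,0.72,0.84,0.5,0.71,0.8,0.44,0.65,0.72,-7.9,-9.4,TRUE
OCT3,Corticosterone,transporter,0.5,0.64,0.82,0.57,0.62,0.77,0.46,0.64,0.71,-10.4,-7.2,TRUE
OATP1B1,Estrone sulfate,transporter,0.57,0.8,0.85,0.68,0.76,0.8,0.56,0.62,0.7,-10.0,-10.1,TRUE
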