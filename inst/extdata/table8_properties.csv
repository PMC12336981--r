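compound_id,TPSA,n_rotatable,MW,LogP,n_HBA,n_HBD,lipinski,veber,egan,muegge,synthetic_accessibility,ames_toxicity
M1,115.55,6,473.55,3.98,9,2,Yes,Yes,Yes,Yes,5.12,No
M2,135.78,6,471.56,3.47,9,3,Yes,Yes,Yes,Yes,5.09,No
M3,115.55,6,469.58,3.98,8,2,Yes,Yes,Yes,Yes,5.15,No
M4,115.55,6,473.55,3.80,9,2,Yes,Yes,Yes,Yes,5.12,No
M5,135.78,6,471.56,3.83,9,2,Yes,Yes,Yes,Yes,5.09,No
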