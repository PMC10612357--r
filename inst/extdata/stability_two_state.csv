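protein,variant,phospho_state,probe,dG_H2O_kcal_mol,dG_se,m_kcal_mol_M,m_se,midpoint_M
MAPK1,WT,NP,CD222,2.51,0.22,0.91,0.09,2.76
MAPK1,WT,NP,avg_wavelength,2.79,0.16,1.34,0.08,2.08
MAPK1,WT,P,CD222,2.30,0.16,0.97,0.07,2.37
MAPK1,WT,P,avg_wavelength,2.88,0.20,1.19,0.09,2.42
MAPK1,Y316F,NP,CD222,2.54,0.23,1.09,0.10,2.32
MAPK1,Y316F,NP,avg_wavelength,2.78,0.25,1.39,0.13,2.00
MAPK1,Y316F,P,CD222,1.46,0.09,0.93,0.05,1.57
MAPK1,Y316F,P,avg_wavelength,2.37,0.19,1.09,0.09,2.17
MAPK1,D162G,NP,CD222,2.28,0.16,1.05,0.08,2.17
MAPK1,D162G,NP,avg_wavelength,2.67,0.12,1.00,0.05,2.68
MAPK1,R135K,P,CD222,2.09,0.17,0.99,0.07,2.12
MAPK1,R135K,P,avg_wavelength,2.38,0.18,1.18,0.09,2.02
MAPK1,R191H,P,CD222,2.31,0.19,1.02,0.09,2.27
MAPK1,R191H,P,avg_wavelength,2.55,0.19,1.35,0.11,1.88
MAPK1,E33Q,NP,CD222,2.44,0.14,0.96,0.06,2.54
MAPK1,E33Q,NP,avg_wavelength,3.33,0.31,1.97,0.20,1.69
MAPK1,L121I,NP,CD222,2.29,0.14,1.00,0.07,2.29
MAPK1,L121I,NP,avg_wavelength,3.27,0.31,1.41,0.14,2.32
MAPK1,L121I,P,CD222,1.73,0.11,1.12,0.07,1.55
MAPK1,L121I,P,avg_wavelength,2.82,0.21,1.46,0.12,1.93
MAPK1,L200F,NP,CD222,2.27,0.16,0.96,0.07,2.36
MAPK1,L200F,NP,avg_wavelength,2.88,0.16,1.44,0.08,2.00
MAPK1,L200F,P,CD222,2.15,0.19,0.97,0.09,2.20
MAPK1,L200F,P,avg_wavelength,3.06,0.30,1.72,0.18,1.77
MAPK1,D235V,NP,CD222,2.46,0.16,1.07,0.08,2.30
MAPK1,D235V,NP,avg_wavelength,2.48,0.19,1.15,0.09,2.15
MAPK1,D235V,P,CD222,1.77,0.11,1.07,0.07,1.65
MAPK1,D235V,P,avg_wavelength,2.41,0.23,1.10,0.12,2.18
MAPK3,WT,NP,CD222,1.84,0.12,0.93,0.07,1.98
MAPK3,WT,NP,avg_wavelength,2.26,0.14,1.11,0.08,2.04
MAPK3,WT,P,CD222,1.72,0.09,0.83,0.04,2.07
MAPK3,WT,P,avg_wavelength,2.40,0.12,1.22,0.06,1.97
MAPK3,T198I,NP,CD222,1.45,0.11,0.99,0.07,1.62
MAPK3,T198I,NP,avg_wavelength,2.31,0.09,1.01,0.42,2.29
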