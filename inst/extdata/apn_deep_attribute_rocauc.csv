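attribute,tox21_5shot,tox21_10shot,sider_5shot,sider_10shot,muv_5shot,muv_10shot,average
CGIP_G,78.81,81.77,72.77,78.69,67.18,67.33,74.43
GraphMVP,78.19,81.52,73.00,76.86,66.26,66.66,73.75
IEM_3d_10conf,79.79,82.70,71.50,77.53,66.68,69.23,74.57
MoleBERT,80.40,84.54,73.20,78.58,66.48,67.35,75.09
molformer,79.60,82.26,73.19,79.05,66.35,67.30,74.63
unimol_10conf,80.66,84.21,73.57,77.08,66.57,67.13,74.87
VideoMol_1conf,79.52,83.66,73.34,78.81,67.39,68.17,75.15
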