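# vendored physics table, see data-raw/make_physics_tables.R
element,shell,binding_eV,fluor_yield,fluor_line_eV,auger_eV,daughter,n_daughters_auger
Pt,K,78394,0.958,66830,54554,L3,2
Pt,L1,13880,0.11,11235,8590,M,2
Pt,L2,13273,0.32,10628,7983,M,2
Pt,L3,11564,0.31,8919,6274,M,2
Pt,M,2645,0.025,2245,1845,N,2
Pt,N,400,0,0,300,none,0
O,K,543,0.0083,525,503,none,0
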