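# vendored physics table, see data-raw/make_physics_tables.R
E_min_eV,E_max_eV,K,L1,L2,L3,M,N
78394,1e+09,0.8,0.028,0.049,0.074,0.038,0.011
13880,78394,0,0.138,0.246,0.37,0.19,0.056
13273,13880,0,0,0.286,0.429,0.22,0.065
11564,13273,0,0,0,0.6,0.3,0.1
2645,11564,0,0,0,0,0.64,0.36
100,2645,0,0,0,0,0,1
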