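# vendored physics table, see data-raw/make_physics_tables.R
energy_eV,value
1.00000000e+02,1.20000000e+00
1.06376485e+02,1.20000000e+00
1.13159567e+02,1.20000000e+00
1.20375170e+02,1.20000000e+00
1.28050875e+02,1.20000000e+00
1.36216020e+02,1.20000000e+00
1.44901815e+02,1.20000000e+00
1.54141458e+02,1.20000000e+00
1.63970266e+02,1.20000000e+00
1.74425806e+02,1.20000000e+00
1.85548042e+02,1.20000000e+00
1.97379486e+02,1.20000000e+00
2.09965360e+02,1.20000000e+00
2.23353771e+02,1.20000000e+00
2.37595891e+02,1.20000000e+00
2.52746159e+02,1.20000000e+00
2.68862481e+02,1.20000000e+00
2.86006458e+02,1.20000000e+00
3.04243618e+02,1.20000000e+00
3.23643668e+02,1.20000000e+00
3.44280759e+02,1.20000000e+00
3.66233771e+02,1.20000000e+00
3.89586614e+02,1.20000000e+00
4.14428548e+02,1.20000000e+00
4.40854524e+02,1.20000000e+00
4.68965549e+02,1.20000000e+00
4.98869069e+02,1.20000000e+00
5.30679382e+02,1.20000000e+00
5.64518076e+02,1.20000000e+00
6.00514488e+02,1.20000000e+00
6.38806207e+02,1.20000000e+00
6.79539592e+02,1.20000000e+00
7.22870335e+02,1.20000000e+00
7.68964057e+02,1.20000000e+00
8.17996938e+02,1.20000000e+00
8.70156393e+02,1.20000000e+00
9.25641789e+02,1.20000000e+00
9.84665203e+02,1.20000000e+00
1.04745224e+03,1.20000000e+00
1.11424288e+03,1.20000000e+00
1.18529241e+03,1.20000000e+00
1.26087241e+03,1.20000000e+00
1.34127175e+03,1.20000000e+00
1.42679775e+03,1.20000000e+00
1.51777730e+03,1.20000000e+00
1.61455815e+03,1.20000000e+00
1.71751022e+03,1.20000000e+00
1.82702700e+03,1.20000000e+00
1.94352711e+03,1.20000000e+00
2.06745584e+03,1.20000000e+00
2.19928686e+03,1.20000000e+00
2.33952406e+03,1.20000000e+00
2.48870348e+03,1.20000000e+00
2.64739529e+03,1.20000000e+00
2.81620607e+03,1.20000000e+00
2.99578103e+03,1.20000000e+00
3.18680658e+03,1.20000000e+00
3.39001283e+03,1.20000000e+00
3.60617651e+03,1.20000000e+00
3.83612383e+03,1.20000000e+00
4.08073370e+03,1.20000000e+00
4.34094109e+03,1.20000000e+00
4.61774057e+03,1.08587221e+00
4.91219013e+03,9.68532699e-01
5.22541521e+03,8.63872915e-01
5.55861305e+03,7.70522684e-01
5.91305720e+03,6.87259891e-01
6.29010244e+03,6.12994488e-01
6.69118990e+03,5.46754215e-01
7.11785265e+03,4.87671876e-01
7.57172149e+03,4.34973982e-01
8.05453121e+03,3.87970631e-01
8.56812721e+03,3.46046469e-01
9.11447260e+03,3.08652637e-01
9.69565562e+03,2.75299589e-01
1.03138977e+04,2.45550676e-01
1.09715619e+04,2.19016434e-01
1.16711619e+04,1.95349487e-01
1.24153719e+04,1.74239993e-01
1.32070362e+04,1.55411594e-01
1.40491810e+04,1.38617795e-01
1.49450249e+04,1.23638736e-01
1.58979923e+04,1.10278316e-01
1.69117254e+04,9.83616255e-02
1.79900992e+04,8.77326540e-02
1.91372352e+04,7.82522508e-02
2.03575182e+04,6.97963012e-02
2.16556124e+04,6.22541029e-02
2.30364794e+04,5.55269155e-02
2.45053971e+04,4.95266690e-02
2.60679802e+04,4.41748100e-02
2.77302012e+04,3.94012737e-02
2.94984134e+04,3.51435663e-02
3.13793754e+04,3.13459475e-02
3.33802767e+04,2.79586999e-02
3.55087652e+04,2.49374787e-02
3.77729765e+04,2.22427312e-02
4.01815648e+04,1.98391784e-02
4.27437364e+04,1.76953540e-02
4.54692846e+04,1.57831914e-02
4.83686269e+04,1.40776575e-02
5.14528453e+04,1.25564238e-02
5.47337285e+04,1.11995748e-02
5.82238167e+04,9.98934716e-03
6.19364499e+04,8.90989686e-03
6.58858186e+04,7.94709212e-03
7.00870182e+04,7.08832820e-03
7.45561067e+04,6.32236243e-03
7.93101660e+04,5.63916703e-03
8.43673672e+04,5.02979783e-03
8.97470401e+04,4.48627715e-03
9.54697470e+04,4.00148939e-03
1.01557362e+05,3.56908787e-03
1.08033152e+05,3.18341172e-03
1.14921870e+05,2.83941179e-03
1.22249846e+05,2.53258454e-03
1.30045090e+05,2.25891309e-03
1.38337396e+05,2.01481462e-03
1.47158460e+05,1.79709346e-03
1.56541998e+05,1.60289928e-03
1.66523876e+05,1.42968975e-03
1.77142246e+05,1.27519727e-03
1.88437696e+05,1.13739927e-03
2.00453398e+05,1.01449174e-03
2.13235280e+05,9.04865617e-04
2.26832196e+05,8.07085708e-04
2.41296118e+05,7.19871910e-04
2.56682330e+05,6.42082447e-04
2.73049642e+05,5.72698925e-04
2.90460612e+05,5.10812997e-04
3.08981791e+05,4.55614471e-04
3.28683970e+05,4.06380705e-04
3.49642455e+05,3.62467147e-04
3.71937355e+05,3.23298895e-04
3.95653887e+05,2.88363170e-04
4.20882699e+05,2.57202604e-04
4.47720223e+05,2.29409254e-04
4.76269038e+05,2.04619257e-04
5.06638264e+05,1.82508070e-04
5.38943979e+05,1.62786222e-04
5.73309663e+05,1.45195519e-04
6.09866670e+05,1.29505670e-04
6.48754729e+05,1.15511269e-04
6.90122480e+05,1.03029105e-04
7.34128040e+05,9.18957646e-05
7.80939607e+05,8.19654950e-05
8.30736107e+05,7.31082918e-05
8.83707874e+05,6.52081992e-05
9.40057378e+05,5.81617918e-05
1.00000000e+06,5.18768202e-05
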