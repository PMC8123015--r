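# vendored physics table, see data-raw/make_physics_tables.R
energy_eV,value
1.00000000e+02,2.22292801e-01
1.06376485e+02,2.22286724e-01
1.13159567e+02,2.22281295e-01
1.20375170e+02,2.22277001e-01
1.28050875e+02,2.22268172e-01
1.36216020e+02,2.22262194e-01
1.44901815e+02,2.22255005e-01
1.54141458e+02,2.22246167e-01
1.63970266e+02,2.22237741e-01
1.74425806e+02,2.22229169e-01
1.85548042e+02,2.22218787e-01
1.97379486e+02,2.22208960e-01
2.09965360e+02,2.22197855e-01
2.23353771e+02,2.22186083e-01
2.37595891e+02,2.22173671e-01
2.52746159e+02,2.22160706e-01
2.68862481e+02,2.22146724e-01
2.86006458e+02,2.22131775e-01
3.04243618e+02,2.22115999e-01
3.23643668e+02,2.22099218e-01
3.44280759e+02,2.22081255e-01
3.66233771e+02,2.22062205e-01
3.89586614e+02,2.22042005e-01
4.14428548e+02,2.22020435e-01
4.40854524e+02,2.21997554e-01
4.68965549e+02,2.21973200e-01
4.98869069e+02,2.21947287e-01
5.30679382e+02,2.21919744e-01
5.64518076e+02,2.21890450e-01
6.00514488e+02,2.21859314e-01
6.38806207e+02,2.21826196e-01
6.79539592e+02,2.21790980e-01
7.22870335e+02,2.21753527e-01
7.68964057e+02,2.21713711e-01
8.17996938e+02,2.21671379e-01
8.70156393e+02,2.21626372e-01
9.25641789e+02,2.21578516e-01
9.84665203e+02,2.21527637e-01
1.04745224e+03,2.21473552e-01
1.11424288e+03,2.21416054e-01
1.18529241e+03,2.21354931e-01
1.26087241e+03,2.21289959e-01
1.34127175e+03,2.21220897e-01
1.42679775e+03,2.21147496e-01
1.51777730e+03,2.21069483e-01
1.61455815e+03,2.20986574e-01
1.71751022e+03,2.20898468e-01
1.82702700e+03,2.20804843e-01
1.94352711e+03,2.20705363e-01
2.06745584e+03,2.20599667e-01
2.19928686e+03,2.20487376e-01
2.33952406e+03,2.20368089e-01
2.48870348e+03,2.20241379e-01
2.64739529e+03,2.20106799e-01
2.81620607e+03,2.19963872e-01
2.99578103e+03,2.19812098e-01
3.18680658e+03,2.19650945e-01
3.39001283e+03,2.19479855e-01
3.60617651e+03,2.19298237e-01
3.83612383e+03,2.19105468e-01
4.08073370e+03,2.18900893e-01
4.34094109e+03,2.18683821e-01
4.61774057e+03,2.18453524e-01
4.91219013e+03,2.18209238e-01
5.22541521e+03,2.17950158e-01
5.55861305e+03,2.17675441e-01
5.91305720e+03,2.17384200e-01
6.29010244e+03,2.17075507e-01
6.69118990e+03,2.16748390e-01
7.11785265e+03,2.16401830e-01
7.57172149e+03,2.16034764e-01
8.05453121e+03,2.15646083e-01
8.56812721e+03,2.15234630e-01
9.11447260e+03,2.14799200e-01
9.69565562e+03,2.14338542e-01
1.03138977e+04,2.13851357e-01
1.09715619e+04,2.13336299e-01
1.16711619e+04,2.12791978e-01
1.24153719e+04,2.12216958e-01
1.32070362e+04,2.11609761e-01
1.40491810e+04,2.10968868e-01
1.49450249e+04,2.10292726e-01
1.58979923e+04,2.09579744e-01
1.69117254e+04,2.08828306e-01
1.79900992e+04,2.08036768e-01
1.91372352e+04,2.07203470e-01
2.03575182e+04,2.06326739e-01
2.16556124e+04,2.05404898e-01
2.30364794e+04,2.04436275e-01
2.45053971e+04,2.03419210e-01
2.60679802e+04,2.02352069e-01
2.77302012e+04,2.01233253e-01
2.94984134e+04,2.00061210e-01
3.13793754e+04,1.98834450e-01
3.33802767e+04,1.97551560e-01
3.55087652e+04,1.96211216e-01
3.77729765e+04,1.94812201e-01
4.01815648e+04,1.93353422e-01
4.27437364e+04,1.91833926e-01
4.54692846e+04,1.90252917e-01
4.83686269e+04,1.88609773e-01
5.14528453e+04,1.86904066e-01
5.47337285e+04,1.85135574e-01
5.82238167e+04,1.83304300e-01
6.19364499e+04,1.81410485e-01
6.58858186e+04,1.79454622e-01
7.00870182e+04,1.77437466e-01
7.45561067e+04,1.75360043e-01
7.93101660e+04,1.73223660e-01
8.43673672e+04,1.71029901e-01
8.97470401e+04,1.68780633e-01
9.54697470e+04,1.66478001e-01
1.01557362e+05,1.64124419e-01
1.08033152e+05,1.61722560e-01
1.14921870e+05,1.59275341e-01
1.22249846e+05,1.56785906e-01
1.30045090e+05,1.54257598e-01
1.38337396e+05,1.51693938e-01
1.47158460e+05,1.49098596e-01
1.56541998e+05,1.46475356e-01
1.66523876e+05,1.43828085e-01
1.77142246e+05,1.41160697e-01
1.88437696e+05,1.38477119e-01
2.00453398e+05,1.35781256e-01
2.13235280e+05,1.33076954e-01
2.26832196e+05,1.30367970e-01
2.41296118e+05,1.27657943e-01
2.56682330e+05,1.24950362e-01
2.73049642e+05,1.22248549e-01
2.90460612e+05,1.19555635e-01
3.08981791e+05,1.16874545e-01
3.28683970e+05,1.14207990e-01
3.49642455e+05,1.11558460e-01
3.71937355e+05,1.08928223e-01
3.95653887e+05,1.06319324e-01
4.20882699e+05,1.03733597e-01
4.47720223e+05,1.01172672e-01
4.76269038e+05,9.86379861e-02
5.06638264e+05,9.61308018e-02
5.38943979e+05,9.36522217e-02
5.73309663e+05,9.12032067e-02
6.09866670e+05,8.87845939e-02
6.48754729e+05,8.63971148e-02
6.90122480e+05,8.40414123e-02
7.34128040e+05,8.17180578e-02
7.80939607e+05,7.94275656e-02
8.30736107e+05,7.71704064e-02
8.83707874e+05,7.49470187e-02
9.40057378e+05,7.27578186e-02
1.00000000e+06,7.06032073e-02
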