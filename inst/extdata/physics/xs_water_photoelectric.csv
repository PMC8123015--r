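# vendored physics table, see data-raw/make_physics_tables.R
energy_eV,value
1.00000000e+02,3.26646841e+06
1.06376485e+02,2.72871172e+06
1.13159567e+02,2.27948559e+06
1.20375170e+02,1.90421528e+06
1.28050875e+02,1.59072549e+06
1.36216020e+02,1.32884533e+06
1.44901815e+02,1.11007834e+06
1.54141458e+02,9.27326828e+05
1.63970266e+02,7.74661583e+05
1.74425806e+02,6.47129523e+05
1.85548042e+02,5.40592988e+05
1.97379486e+02,4.51595497e+05
2.09965360e+02,3.77249608e+05
2.23353771e+02,3.15143238e+05
2.37595891e+02,2.63261400e+05
2.52746159e+02,2.19920838e+05
2.68862481e+02,1.83715406e+05
2.86006458e+02,1.53470452e+05
3.04243618e+02,1.28204706e+05
3.23643668e+02,1.07098444e+05
3.44280759e+02,8.94668928e+04
3.66233771e+02,7.47380133e+04
3.89586614e+02,6.24339402e+04
4.14428548e+02,5.21554790e+04
4.40854524e+02,4.35691546e+04
4.68965549e+02,3.63963915e+04
4.98869069e+02,3.04044760e+04
5.30679382e+02,2.53990058e+04
5.64518076e+02,2.12175831e+04
6.00514488e+02,1.77245454e+04
6.38806207e+02,1.48065644e+04
6.79539592e+02,1.23689688e+04
7.22870335e+02,1.03326731e+04
7.68964057e+02,8.63161150e+03
8.17996938e+02,7.21059461e+03
8.70156393e+02,6.02351886e+03
9.25641789e+02,5.03187065e+03
9.84665203e+02,4.20347688e+03
1.04745224e+03,3.51146107e+03
1.11424288e+03,2.93337140e+03
1.18529241e+03,2.45045227e+03
1.26087241e+03,2.04703582e+03
1.34127175e+03,1.71003357e+03
1.42679775e+03,1.42851180e+03
1.51777730e+03,1.19333678e+03
1.61455815e+03,9.96878479e+02
1.71751022e+03,8.32762989e+02
1.82702700e+03,6.95665730e+02
1.94352711e+03,5.81138709e+02
2.06745584e+03,4.85466201e+02
2.19928686e+03,4.05544199e+02
2.33952406e+03,3.38779707e+02
2.48870348e+03,2.83006612e+02
2.64739529e+03,2.36415408e+02
2.81620607e+03,1.97494485e+02
2.99578103e+03,1.64981089e+02
3.18680658e+03,1.37820354e+02
3.39001283e+03,1.15131074e+02
3.60617651e+03,9.61771161e+01
3.83612383e+03,8.03435367e+01
4.08073370e+03,6.71166297e+01
4.34094109e+03,5.60672602e+01
4.61774057e+03,4.68369417e+01
4.91219013e+03,3.91262048e+01
5.22541521e+03,3.26848818e+01
5.55861305e+03,2.73039898e+01
5.91305720e+03,2.28089508e+01
6.29010244e+03,1.90539272e+01
6.69118990e+03,1.59170909e+01
7.11785265e+03,1.32966700e+01
7.57172149e+03,1.11076474e+01
8.05453121e+03,9.27900227e+00
8.56812721e+03,7.75140583e+00
9.11447260e+03,6.47529666e+00
9.69565562e+03,5.40927256e+00
1.03138977e+04,4.47151097e+00
1.09715619e+04,3.65768228e+00
1.16711619e+04,2.99197291e+00
1.24153719e+04,2.44742468e+00
1.32070362e+04,2.00198589e+00
1.40491810e+04,1.63761833e+00
1.49450249e+04,1.33956678e+00
1.58979923e+04,1.09576152e+00
1.69117254e+04,8.96329569e-01
1.79900992e+04,7.33194843e-01
1.91372352e+04,5.99751136e-01
2.03575182e+04,4.90594593e-01
2.16556124e+04,4.01304875e-01
2.30364794e+04,3.28266159e-01
2.45053971e+04,2.68520713e-01
2.60679802e+04,2.19649121e-01
2.77302012e+04,1.79672308e-01
2.94984134e+04,1.46971398e-01
3.13793754e+04,1.20222153e-01
3.33802767e+04,9.83413532e-02
3.55087652e+04,8.04429258e-02
3.77729765e+04,6.58020670e-02
4.01815648e+04,5.38258893e-02
4.27437364e+04,4.40294126e-02
4.54692846e+04,3.60159247e-02
4.83686269e+04,2.94609161e-02
5.14528453e+04,2.40989392e-02
5.47337285e+04,1.97128584e-02
5.82238167e+04,1.61250578e-02
6.19364499e+04,1.31902479e-02
6.58858186e+04,1.07895824e-02
7.00870182e+04,8.82584537e-03
7.45561067e+04,7.21951449e-03
7.93101660e+04,5.90554074e-03
8.43673672e+04,4.83071424e-03
8.97470401e+04,3.95150946e-03
9.54697470e+04,3.23232264e-03
1.01557362e+05,2.64403002e-03
1.08033152e+05,2.16280846e-03
1.14921870e+05,1.76917070e-03
1.22249846e+05,1.44717621e-03
1.30045090e+05,1.18378571e-03
1.38337396e+05,9.68333085e-04
1.47158460e+05,7.92093499e-04
1.56541998e+05,6.47930056e-04
1.66523876e+05,5.30004802e-04
1.77142246e+05,4.33542305e-04
1.88437696e+05,3.54636278e-04
2.00453398e+05,2.90091389e-04
2.13235280e+05,2.37293868e-04
2.26832196e+05,1.94105657e-04
2.41296118e+05,1.58777833e-04
2.56682330e+05,1.29879781e-04
2.73049642e+05,1.06241264e-04
2.90460612e+05,8.69050282e-05
3.08981791e+05,7.10880470e-05
3.28683970e+05,5.81498047e-05
3.49642455e+05,4.75663622e-05
3.71937355e+05,3.89091386e-05
3.95653887e+05,3.18275562e-05
4.20882699e+05,2.60348435e-05
4.47720223e+05,2.12964223e-05
4.76269038e+05,1.74204082e-05
5.06638264e+05,1.42498406e-05
5.38943979e+05,1.16563260e-05
5.73309663e+05,9.53483894e-06
6.09866670e+05,7.79946905e-06
6.48754729e+05,6.37994180e-06
6.90122480e+05,5.21877286e-06
7.34128040e+05,4.26894022e-06
7.80939607e+05,3.49198002e-06
8.30736107e+05,2.85642897e-06
8.83707874e+05,2.33655015e-06
9.40057378e+05,1.91129087e-06
1.00000000e+06,1.56343008e-06
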