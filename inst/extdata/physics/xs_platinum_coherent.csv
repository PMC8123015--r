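# vendored physics table, see data-raw/make_physics_tables.R
energy_eV,value
1.00000000e+02,3.99992149e+00
1.06376485e+02,3.99991116e+00
1.13159567e+02,3.99989947e+00
1.20375170e+02,3.99988624e+00
1.28050875e+02,3.99987127e+00
1.36216020e+02,3.99985433e+00
1.44901815e+02,3.99983516e+00
1.54141458e+02,3.99981347e+00
1.63970266e+02,3.99978892e+00
1.74425806e+02,3.99976115e+00
1.85548042e+02,3.99972972e+00
1.97379486e+02,3.99969415e+00
2.09965360e+02,3.99965391e+00
2.23353771e+02,3.99960837e+00
2.37595891e+02,3.99955683e+00
2.52746159e+02,3.99949852e+00
2.68862481e+02,3.99943254e+00
2.86006458e+02,3.99935788e+00
3.04243618e+02,3.99927339e+00
3.23643668e+02,3.99917779e+00
3.44280759e+02,3.99906962e+00
3.66233771e+02,3.99894722e+00
3.89586614e+02,3.99880872e+00
4.14428548e+02,3.99865201e+00
4.40854524e+02,3.99847469e+00
4.68965549e+02,3.99827405e+00
4.98869069e+02,3.99804704e+00
5.30679382e+02,3.99779018e+00
5.64518076e+02,3.99749957e+00
6.00514488e+02,3.99717076e+00
6.38806207e+02,3.99679875e+00
6.79539592e+02,3.99637787e+00
7.22870335e+02,3.99590172e+00
7.68964057e+02,3.99536304e+00
8.17996938e+02,3.99475366e+00
8.70156393e+02,3.99406431e+00
9.25641789e+02,3.99328455e+00
9.84665203e+02,3.99240255e+00
1.04745224e+03,3.99140496e+00
1.11424288e+03,3.99027671e+00
1.18529241e+03,3.98900078e+00
1.26087241e+03,3.98755795e+00
1.34127175e+03,3.98592654e+00
1.42679775e+03,3.98408210e+00
1.51777730e+03,3.98199705e+00
1.61455815e+03,3.97964031e+00
1.71751022e+03,3.97697689e+00
1.82702700e+03,3.97396739e+00
1.94352711e+03,3.97056748e+00
2.06745584e+03,3.96672734e+00
2.19928686e+03,3.96239105e+00
2.33952406e+03,3.95749584e+00
2.48870348e+03,3.95197139e+00
2.64499735e+03,3.94583590e+00
2.64500000e+03,3.94583579e+00
2.64739529e+03,3.94573901e+00
2.81620607e+03,3.93871076e+00
2.99578103e+03,3.93078854e+00
3.18680658e+03,3.92186316e+00
3.39001283e+03,3.91181326e+00
3.60617651e+03,3.90050440e+00
3.83612383e+03,3.88778801e+00
4.08073370e+03,3.87350042e+00
4.34094109e+03,3.85746208e+00
4.61774057e+03,3.83947674e+00
4.91219013e+03,3.81933107e+00
5.22541521e+03,3.79679436e+00
5.55861305e+03,3.77161884e+00
5.91305720e+03,3.74354035e+00
6.29010244e+03,3.71227980e+00
6.69118990e+03,3.67754538e+00
7.11785265e+03,3.63903576e+00
7.57172149e+03,3.59644446e+00
8.05453121e+03,3.54946544e+00
8.56812721e+03,3.49780015e+00
9.11447260e+03,3.44116597e+00
9.69565562e+03,3.37930618e+00
1.03138977e+04,3.31200121e+00
1.09715619e+04,3.23908095e+00
1.15639884e+04,3.17254004e+00
1.15640000e+04,3.17253874e+00
1.16711619e+04,3.16043785e+00
1.24153719e+04,3.07603996e+00
1.32070362e+04,2.98594348e+00
1.32729867e+04,2.97843913e+00
1.32730000e+04,2.97843762e+00
1.38799861e+04,2.90947584e+00
1.38800000e+04,2.90947427e+00
1.40491810e+04,2.89030373e+00
1.49450249e+04,2.78938362e+00
1.58979923e+04,2.68355870e+00
1.69117254e+04,2.57331787e+00
1.79900992e+04,2.45925907e+00
1.91372352e+04,2.34207960e+00
2.03575182e+04,2.22256115e+00
2.16556124e+04,2.10155008e+00
2.30364794e+04,1.97993390e+00
2.45053971e+04,1.85861524e+00
2.60679802e+04,1.73848512e+00
2.77302012e+04,1.62039690e+00
2.94984134e+04,1.50514279e+00
3.13793754e+04,1.39343405e+00
3.33802767e+04,1.28588594e+00
3.55087652e+04,1.18300776e+00
3.77729765e+04,1.08519829e+00
4.01815648e+04,9.92745958e-01
4.27437364e+04,9.05833370e-01
4.54692846e+04,8.24545132e-01
4.83686269e+04,7.48878161e-01
5.14528453e+04,6.78753505e-01
5.47337285e+04,6.14028832e-01
5.82238167e+04,5.54510894e-01
6.19364499e+04,4.99967414e-01
6.58858186e+04,4.50137993e-01
7.00870182e+04,4.04743799e-01
7.45561067e+04,3.63495919e-01
7.83939216e+04,3.32850867e-01
7.83940000e+04,3.32850281e-01
7.93101660e+04,3.26102339e-01
8.43673672e+04,2.92273614e-01
8.97470401e+04,2.61727329e-01
9.54697470e+04,2.34191464e-01
1.01557362e+05,2.09406828e-01
1.08033152e+05,1.87128689e-01
1.14921870e+05,1.67127756e-01
1.22249846e+05,1.49190623e-01
1.30045090e+05,1.33119803e-01
1.38337396e+05,1.18733442e-01
1.47158460e+05,1.05864798e-01
1.56541998e+05,9.43615563e-02
1.66523876e+05,8.40850360e-02
1.77142246e+05,7.49093266e-02
1.88437696e+05,6.67203986e-02
2.00453398e+05,5.94152073e-02
2.13235280e+05,5.29008140e-02
2.26832196e+05,4.70935356e-02
2.41296118e+05,4.19181350e-02
2.56682330e+05,3.73070566e-02
2.73049642e+05,3.31997118e-02
2.90460612e+05,2.95418156e-02
3.08981791e+05,2.62847737e-02
3.28683970e+05,2.33851208e-02
3.49642455e+05,2.08040054e-02
3.71937355e+05,1.85067218e-02
3.95653887e+05,1.64622844e-02
4.20882699e+05,1.46430418e-02
4.47720223e+05,1.30243287e-02
4.76269038e+05,1.15841514e-02
5.06638264e+05,1.03029047e-02
5.38943979e+05,9.16311805e-03
5.73309663e+05,8.14922661e-03
6.09866670e+05,7.24736672e-03
6.48754729e+05,6.44519239e-03
6.90122480e+05,5.73171106e-03
7.34128040e+05,5.09713680e-03
7.80939607e+05,4.53275902e-03
8.30736107e+05,4.03082523e-03
8.83707874e+05,3.58443644e-03
9.40057378e+05,3.18745375e-03
1.00000000e+06,2.83441505e-03
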