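# vendored physics table, see data-raw/make_physics_tables.R
energy_eV,value
1.00000000e+02,2.73512133e+05
1.06376485e+02,2.57117099e+05
1.13159567e+02,2.41704826e+05
1.20375170e+02,2.27216405e+05
1.28050875e+02,2.13596458e+05
1.36216020e+02,2.00792926e+05
1.44901815e+02,1.88756872e+05
1.54141458e+02,1.77442290e+05
1.63970266e+02,1.66805934e+05
1.74425806e+02,1.56807149e+05
1.85548042e+02,1.47407717e+05
1.97379486e+02,1.38571712e+05
2.09965360e+02,1.30265361e+05
2.23353771e+02,1.22456913e+05
2.37595891e+02,1.15116525e+05
2.52746159e+02,1.08216139e+05
2.68862481e+02,1.01729380e+05
2.86006458e+02,9.56314538e+04
3.04243618e+02,8.98990538e+04
3.23643668e+02,8.45102688e+04
3.44280759e+02,7.94445017e+04
3.66233771e+02,7.46823900e+04
3.89586614e+02,7.02057317e+04
4.14428548e+02,6.32498245e+04
4.40854524e+02,5.52076069e+04
4.68965549e+02,4.81879576e+04
4.98869069e+02,4.20608570e+04
5.30679382e+02,3.67128174e+04
5.64518076e+02,3.20447813e+04
6.00514488e+02,2.79702861e+04
6.38806207e+02,2.44138632e+04
6.79539592e+02,2.13096395e+04
7.22870335e+02,1.86001181e+04
7.68964057e+02,1.62351123e+04
8.17996938e+02,1.41708172e+04
8.70156393e+02,1.23689972e+04
9.25641789e+02,1.07962788e+04
9.84665203e+02,9.42353152e+03
1.04745224e+03,8.22532912e+03
1.11424288e+03,7.17947821e+03
1.18529241e+03,6.26660729e+03
1.26087241e+03,5.46980793e+03
1.34127175e+03,4.77432164e+03
1.42679775e+03,4.16726647e+03
1.51777730e+03,3.63739838e+03
1.61455815e+03,3.17490303e+03
1.71751022e+03,2.77121399e+03
1.82702700e+03,2.41885403e+03
1.94352711e+03,2.11129665e+03
2.06745584e+03,1.84284520e+03
2.19928686e+03,1.60852736e+03
2.33952406e+03,1.40400305e+03
2.48870348e+03,1.22548400e+03
2.64499735e+03,1.07179828e+03
2.64500000e+03,3.00102857e+03
2.64739529e+03,2.99410954e+03
2.81620607e+03,2.55747448e+03
2.99578103e+03,2.18451451e+03
3.18680658e+03,1.86594379e+03
3.39001283e+03,1.59383068e+03
3.60617651e+03,1.36140019e+03
3.83612383e+03,1.16286535e+03
4.08073370e+03,9.93283118e+02
4.34094109e+03,8.48431293e+02
4.61774057e+03,7.24703406e+02
4.91219013e+03,6.19018925e+02
5.22541521e+03,5.28746555e+02
5.55861305e+03,4.51638728e+02
5.91305720e+03,3.85775639e+02
6.29010244e+03,3.29517454e+02
6.69118990e+03,2.81463477e+02
7.11785265e+03,2.40417276e+02
7.57172149e+03,2.05356898e+02
8.05453121e+03,1.75409423e+02
8.56812721e+03,1.49829229e+02
9.11447260e+03,1.27979429e+02
9.69565562e+03,1.09316015e+02
1.03138977e+04,9.33743124e+01
1.09715619e+04,7.97574097e+01
1.15639884e+04,6.97478943e+01
1.15640000e+04,1.74369291e+02
1.16711619e+04,1.70158666e+02
1.24153719e+04,1.44448532e+02
1.32070362e+04,1.22623072e+02
1.32729867e+04,1.21015074e+02
1.32730000e+04,1.69420655e+02
1.38799861e+04,1.50488573e+02
1.38800000e+04,1.74566282e+02
1.40491810e+04,1.69050819e+02
1.49450249e+04,1.43508075e+02
1.58979923e+04,1.21824714e+02
1.69117254e+04,1.03417601e+02
1.79900992e+04,8.77917125e+01
1.91372352e+04,7.45268183e+01
2.03575182e+04,6.32661842e+01
2.16556124e+04,5.37069762e+01
2.30364794e+04,4.55921174e+01
2.45053971e+04,3.87033736e+01
2.60679802e+04,3.28554850e+01
2.77302012e+04,2.78911835e+01
2.94984134e+04,2.36769634e+01
3.13793754e+04,2.00994912e+01
3.33802767e+04,1.70625574e+01
3.55087652e+04,1.44844892e+01
3.77729765e+04,1.22959544e+01
4.01815648e+04,1.04380965e+01
4.27437364e+04,8.86095163e+00
4.54692846e+04,7.52210561e+00
4.83686269e+04,6.38555260e+00
5.14528453e+04,5.42072714e+00
5.47337285e+04,4.60168205e+00
5.82238167e+04,3.90639062e+00
6.19364499e+04,3.31615429e+00
6.58858186e+04,2.81509975e+00
7.00870182e+04,2.38975209e+00
7.45561067e+04,2.02867235e+00
7.83939216e+04,1.77600471e+00
7.83940000e+04,8.88000000e+00
7.93101660e+04,8.59651883e+00
8.43673672e+04,7.23369052e+00
8.97470401e+04,6.08691489e+00
9.54697470e+04,5.12194057e+00
1.01557362e+05,4.31326053e+00
1.08033152e+05,3.64064558e+00
1.14921870e+05,3.07291900e+00
1.22249846e+05,2.59372437e+00
1.30045090e+05,2.18925592e+00
1.38337396e+05,1.84786076e+00
1.47158460e+05,1.55970317e+00
1.56541998e+05,1.31462549e+00
1.66523876e+05,1.10735706e+00
1.77142246e+05,9.32767291e-01
1.88437696e+05,7.85703954e-01
2.00453398e+05,6.62024869e-01
2.13235280e+05,5.62213716e-01
2.26832196e+05,4.77450739e-01
2.41296118e+05,4.05467176e-01
2.56682330e+05,3.44336321e-01
2.73049642e+05,2.92421950e-01
2.90460612e+05,2.48334525e-01
3.08981791e+05,2.12413830e-01
3.28683970e+05,1.83123711e-01
3.49642455e+05,1.57872458e-01
3.71937355e+05,1.36103145e-01
3.95653887e+05,1.17335641e-01
4.20882699e+05,1.01156021e-01
4.47720223e+05,8.72074382e-02
4.76269038e+05,7.51822500e-02
5.06638264e+05,6.48939226e-02
5.38943979e+05,5.62646151e-02
5.73309663e+05,4.87827948e-02
6.09866670e+05,4.22958740e-02
6.48754729e+05,3.66715552e-02
6.90122480e+05,3.19332965e-02
7.34128040e+05,2.78658939e-02
7.80939607e+05,2.43165639e-02
8.30736107e+05,2.12193186e-02
8.83707874e+05,1.85165750e-02
9.40057378e+05,1.61580849e-02
1.00000000e+06,1.41000000e-02
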