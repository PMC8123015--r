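# vendored physics table, see data-raw/make_physics_tables.R
energy_eV,value
1.00000000e+02,1.60116079e-01
1.06376485e+02,1.60111701e-01
1.13159567e+02,1.60107791e-01
1.20375170e+02,1.60104698e-01
1.28050875e+02,1.60098339e-01
1.36216020e+02,1.60094032e-01
1.44901815e+02,1.60088855e-01
1.54141458e+02,1.60082489e-01
1.63970266e+02,1.60076420e-01
1.74425806e+02,1.60070245e-01
1.85548042e+02,1.60062767e-01
1.97379486e+02,1.60055688e-01
2.09965360e+02,1.60047690e-01
2.23353771e+02,1.60039210e-01
2.37595891e+02,1.60030270e-01
2.52746159e+02,1.60020932e-01
2.68862481e+02,1.60010861e-01
2.86006458e+02,1.60000093e-01
3.04243618e+02,1.59988729e-01
3.23643668e+02,1.59976642e-01
3.44280759e+02,1.59963703e-01
3.66233771e+02,1.59949982e-01
3.89586614e+02,1.59935432e-01
4.14428548e+02,1.59919895e-01
4.40854524e+02,1.59903414e-01
4.68965549e+02,1.59885872e-01
4.98869069e+02,1.59867207e-01
5.30679382e+02,1.59847368e-01
5.64518076e+02,1.59826268e-01
6.00514488e+02,1.59803841e-01
6.38806207e+02,1.59779986e-01
6.79539592e+02,1.59754620e-01
7.22870335e+02,1.59727643e-01
7.68964057e+02,1.59698964e-01
8.17996938e+02,1.59668473e-01
8.70156393e+02,1.59636054e-01
9.25641789e+02,1.59601583e-01
9.84665203e+02,1.59564936e-01
1.04745224e+03,1.59525979e-01
1.11424288e+03,1.59484563e-01
1.18529241e+03,1.59440537e-01
1.26087241e+03,1.59393738e-01
1.34127175e+03,1.59343993e-01
1.42679775e+03,1.59291123e-01
1.51777730e+03,1.59234931e-01
1.61455815e+03,1.59175212e-01
1.71751022e+03,1.59111749e-01
1.82702700e+03,1.59044312e-01
1.94352711e+03,1.58972657e-01
2.06745584e+03,1.58896525e-01
2.19928686e+03,1.58815643e-01
2.33952406e+03,1.58729721e-01
2.48870348e+03,1.58638453e-01
2.64499735e+03,1.58542979e-01
2.64500000e+03,1.58542977e-01
2.64739529e+03,1.58541515e-01
2.81620607e+03,1.58438566e-01
2.99578103e+03,1.58329244e-01
3.18680658e+03,1.58213167e-01
3.39001283e+03,1.58089932e-01
3.60617651e+03,1.57959113e-01
3.83612383e+03,1.57820263e-01
4.08073370e+03,1.57672909e-01
4.34094109e+03,1.57516553e-01
4.61774057e+03,1.57350672e-01
4.91219013e+03,1.57174714e-01
5.22541521e+03,1.56988101e-01
5.55861305e+03,1.56790224e-01
5.91305720e+03,1.56580445e-01
6.29010244e+03,1.56358095e-01
6.69118990e+03,1.56122475e-01
7.11785265e+03,1.55872850e-01
7.57172149e+03,1.55608455e-01
8.05453121e+03,1.55328490e-01
8.56812721e+03,1.55032123e-01
9.11447260e+03,1.54718486e-01
9.69565562e+03,1.54386677e-01
1.03138977e+04,1.54035761e-01
1.09715619e+04,1.53664768e-01
1.15639884e+04,1.53332588e-01
1.15640000e+04,1.53332581e-01
1.16711619e+04,1.53272697e-01
1.24153719e+04,1.52858514e-01
1.32070362e+04,1.52421153e-01
1.32729867e+04,1.52384868e-01
1.32730000e+04,1.52384860e-01
1.38799861e+04,1.52051971e-01
1.38800000e+04,1.52051964e-01
1.40491810e+04,1.51959523e-01
1.49450249e+04,1.51472502e-01
1.58979923e+04,1.50958946e-01
1.69117254e+04,1.50417689e-01
1.79900992e+04,1.49847550e-01
1.91372352e+04,1.49247330e-01
2.03575182e+04,1.48615827e-01
2.16556124e+04,1.47951831e-01
2.30364794e+04,1.47254138e-01
2.45053971e+04,1.46521552e-01
2.60679802e+04,1.45752898e-01
2.77302012e+04,1.44947021e-01
2.94984134e+04,1.44102806e-01
3.13793754e+04,1.43219179e-01
3.33802767e+04,1.42295122e-01
3.55087652e+04,1.41329680e-01
3.77729765e+04,1.40321979e-01
4.01815648e+04,1.39271229e-01
4.27437364e+04,1.38176746e-01
4.54692846e+04,1.37037955e-01
4.83686269e+04,1.35854410e-01
5.14528453e+04,1.34625800e-01
5.47337285e+04,1.33351967e-01
5.82238167e+04,1.32032912e-01
6.19364499e+04,1.30668809e-01
6.58858186e+04,1.29260013e-01
7.00870182e+04,1.27807068e-01
7.45561067e+04,1.26310714e-01
7.83939216e+04,1.25064352e-01
7.83940000e+04,1.25064327e-01
7.93101660e+04,1.24771891e-01
8.43673672e+04,1.23191741e-01
8.97470401e+04,1.21571607e-01
9.54697470e+04,1.19913036e-01
1.01557362e+05,1.18217766e-01
1.08033152e+05,1.16487722e-01
1.14921870e+05,1.14725007e-01
1.22249846e+05,1.12931882e-01
1.30045090e+05,1.11110758e-01
1.38337396e+05,1.09264171e-01
1.47158460e+05,1.07394762e-01
1.56541998e+05,1.05505259e-01
1.66523876e+05,1.03598447e-01
1.77142246e+05,1.01677144e-01
1.88437696e+05,9.97441806e-02
2.00453398e+05,9.78023676e-02
2.13235280e+05,9.58544761e-02
2.26832196e+05,9.39032127e-02
2.41296118e+05,9.19511974e-02
2.56682330e+05,9.00009446e-02
2.73049642e+05,8.80548460e-02
2.90460612e+05,8.61151569e-02
3.08981791e+05,8.41839849e-02
3.28683970e+05,8.22632826e-02
3.49642455e+05,8.03548435e-02
3.71937355e+05,7.84603002e-02
3.95653887e+05,7.65811273e-02
4.20882699e+05,7.47186449e-02
4.47720223e+05,7.28740267e-02
4.76269038e+05,7.10483087e-02
5.06638264e+05,6.92423999e-02
5.38943979e+05,6.74570946e-02
5.73309663e+05,6.56930848e-02
6.09866670e+05,6.39509735e-02
6.48754729e+05,6.22312876e-02
6.90122480e+05,6.05344902e-02
7.34128040e+05,5.88609929e-02
7.80939607e+05,5.72111661e-02
8.30736107e+05,5.55853487e-02
8.83707874e+05,5.39838568e-02
9.40057378e+05,5.24069901e-02
1.00000000e+06,5.08550373e-02
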