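MWB,QoL,DEP,SE,HEA,PND
58.810000000000002,101.48999999999999,11.58,35.240000000000002,80.700000000000003,7
49.350000000000001,80.379999999999995,11.34,31.899999999999999,74.010000000000005,0
61.009999999999998,93.790000000000006,19.75,34.200000000000003,105.8,0
47.799999999999997,105.42,-1.6100000000000001,27.579999999999998,57.039999999999999,3
49.340000000000003,80.090000000000003,16.84,30.350000000000001,69.599999999999994,4
49.799999999999997,102.08,10.880000000000001,32.210000000000001,74.019999999999996,1
61.340000000000003,95.590000000000003,17.82,35.57,87.019999999999996,1
41.149999999999999,80.849999999999994,12.029999999999999,38.409999999999997,81.579999999999998,0
52.289999999999999,94.900000000000006,12.130000000000001,27.75,62.289999999999999,3
51.560000000000002,89.310000000000002,18.789999999999999,32.020000000000003,90.189999999999998,0
55,87.870000000000005,20.120000000000001,34.719999999999999,79.969999999999999,0
71.140000000000001,107.66,20.559999999999999,35.240000000000002,116.06999999999999,5
49.350000000000001,93.760000000000005,14.44,37.43,76.549999999999997,0
50.789999999999999,88.640000000000001,18.16,35.450000000000003,86.790000000000006,0
57.899999999999999,96.209999999999994,22.530000000000001,43.590000000000003,100.5,1
44.509999999999998,88.890000000000001,11.84,29.260000000000002,66.049999999999997,5
48.149999999999999,96.840000000000003,9.9499999999999993,30.370000000000001,68.379999999999995,5
65.379999999999995,99.840000000000003,21.870000000000001,33.810000000000002,120.64,4
60.840000000000003,93.719999999999999,25.109999999999999,39.310000000000002,108.69,0
56.450000000000003,99.769999999999996,16.629999999999999,33.770000000000003,59.490000000000002,0
55.450000000000003,84.230000000000004,17.170000000000002,36.020000000000003,82.590000000000003,4
56.130000000000003,83.909999999999997,17.440000000000001,26.09,75.969999999999999,0
42.369999999999997,67.870000000000005,7.0300000000000002,31.59,54.159999999999997,1
44.829999999999998,100.73,5.9400000000000004,29.710000000000001,51.789999999999999,0
50.920000000000002,91.469999999999999,13.609999999999999,34.219999999999999,75.060000000000002,2
50.020000000000003,93.549999999999997,11.369999999999999,28.09,77.680000000000007,3
56.960000000000001,96.170000000000002,23.98,34,99.799999999999997,5
54.869999999999997,89.900000000000006,20.140000000000001,30.890000000000001,85.480000000000004,3
50.130000000000003,93.590000000000003,18.219999999999999,31.719999999999999,80.049999999999997,5
54.149999999999999,77.989999999999995,18.18,25.100000000000001,64.689999999999998,3
47.009999999999998,84.829999999999998,13.529999999999999,30.879999999999999,79.269999999999996,4
55.030000000000001,92.760000000000005,13.56,34.909999999999997,69.870000000000005,1
57.549999999999997,85.590000000000003,23.010000000000002,37.810000000000002,106.23999999999999,2
51.710000000000001,81.189999999999998,8.5299999999999994,25.690000000000001,61.659999999999997,5
58.049999999999997,95.890000000000001,15.119999999999999,35.82,81.909999999999997,3
45.18,79.219999999999999,11.94,26.699999999999999,59.399999999999999,3
55.520000000000003,118.25,17.030000000000001,43.560000000000002,103.53,0
51.5,80.980000000000004,17.140000000000001,28.600000000000001,67.280000000000001,0
54.890000000000001,91.060000000000002,17.68,33.740000000000002,87.420000000000002,4
52.619999999999997,85.730000000000004,18.98,34.649999999999999,77.939999999999998,7
63.890000000000001,88.310000000000002,23.32,40.009999999999998,105.70999999999999,2
54.700000000000003,112.26000000000001,16.219999999999999,33.270000000000003,72.370000000000005,0
58.310000000000002,103.98,22.84,34.670000000000002,102.69,0
57.850000000000001,109.56,18.48,35.07,97.659999999999997,5
62.009999999999998,109.98999999999999,15.5,40.090000000000003,96.859999999999999,0
53.630000000000003,91.200000000000003,23.109999999999999,35.439999999999998,92.030000000000001,0
53.630000000000003,94.620000000000005,14.33,31.960000000000001,80.099999999999994,2
44.840000000000003,94.299999999999997,15.43,32.130000000000003,78.920000000000002,1
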