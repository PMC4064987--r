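time_min,artery_signal,tissue_signal
-3.23333333333333,500,1000
-1.61666666666667,500,1000
0,1321.59,1000
1.61666666666667,1128.267,1086.969
3.23333333333333,1011.562,1138.019
4.85,947.374,1172.046
6.46666666666667,911.473,1197.018
8.08333333333333,889.447,1216.522
9.7,874.007,1232.285
11.3166666666667,861.695,1245.221
12.9333333333333,850.918,1255.866
14.55,840.95,1264.577
16.1666666666667,831.459,1271.616
17.7833333333333,822.297,1277.19
19.4,813.393,1281.473
21.0166666666667,804.717,1290.127
22.6333333333333,796.252,1301.051
24.25,787.991,1311.07
25.8666666666667,779.927,1320.244
27.4833333333333,772.057,1328.628
29.1,764.378,1336.272
30.7166666666667,756.887,1343.223
32.3333333333333,749.58,1349.524
33.95,742.456,1355.215
35.5666666666667,735.511,1360.333
37.1833333333333,728.742,1364.913
38.8,722.146,1368.985
40.4166666666667,715.719,1372.58
42.0333333333333,709.459,1375.725
43.65,703.363,1378.447
45.2666666666667,697.427,1380.769
46.8833333333333,691.649,1382.714
48.5,686.024,1384.303
50.1166666666667,680.55,1385.556
51.7333333333333,675.224,1386.492
53.35,670.043,1387.128
54.9666666666667,665.002,1387.482
56.5833333333333,660.1,1387.567
58.2,655.334,1387.4
59.8166666666667,650.699,1386.994
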