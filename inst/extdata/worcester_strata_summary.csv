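unit_id,name,scale,stratum,town_no,population,stratum_pop,mos,stratum_mos,h_s,a_s,h_class,a_class,n_block_groups,min_bg_pop,max_bg_pop,mean_bg_hs,sd_bg_hs,mean_bg_as,sd_bg_as
athol,Athol,town,1,1,11299,NA,531,NA,0.936,6.46,4,4,8,1039,2092,0.150,0.155,7.40,0.364
gardner,Gardner,town,1,2,20770,NA,917,NA,2.265,4.63,5,2,12,706,2512,0.330,0.375,7.04,0.340
royalston,Royalston,town,1,3,1254,NA,41,NA,0.005,7.11,2,5,1,1254,1254,0.005,0.000,7.11,0.000
winchendon,Winchendon,town,1,5,9611,42934,479,1969,2.007,4.24,5,2,7,643,2230,0.250,0.264,7.39,0.341
barre,Barre,town,2,16,5113,NA,232,NA,0.730,5.55,4,3,4,804,1595,0.090,0.113,7.50,0.239
e_brookfield,E. Brookfield,town,2,22,2097,NA,80,NA,0.543,6.33,4,4,2,687,1410,0.080,0.092,7.76,0.127
holden,Holden,town,2,17,15621,NA,670,NA,0.868,6.21,4,4,13,667,1978,0.140,0.090,7.25,0.279
n_brookfield,N. Brookfield,town,2,24,4683,NA,176,NA,0.965,5.39,4,3,5,661,1380,0.140,0.126,7.40,0.224
oakham,Oakham,town,2,10,1673,NA,77,NA,0.030,7.49,2,5,1,1673,1673,0.030,0.000,7.49,0.000
rutland,Rutland,town,2,19,6353,NA,339,NA,0.271,6.26,3,4,3,1329,2819,0.040,0.036,7.43,0.422
spencer,Spencer,town,2,25,11691,NA,513,NA,1.338,6.15,4,4,10,637,1870,0.200,0.226,7.37,0.490
w_boylston,W. Boylston,town,2,20,7481,54712,224,2310,1.210,5.72,4,3,8,547,2509,0.170,0.162,7.34,0.342
charlton,Charlton,town,3,28,11263,NA,591,NA,0.659,6.68,4,4,6,527,2925,0.080,0.083,7.56,0.166
leicester,Leicester,town,3,23,10471,NA,429,NA,0.470,6.57,3,4,8,914,2410,0.070,0.043,7.43,0.344
oxford,Oxford,town,3,29,13352,NA,580,NA,1.123,7.48,4,5,9,565,2882,0.150,0.108,7.68,0.349
paxton,Paxton,town,3,18,4386,NA,148,NA,0.499,6.30,3,4,4,614,1492,0.070,0.062,7.16,0.274
sturbridge,Sturbridge,town,3,30,7837,47309,353,2101,0.550,7.76,4,5,6,1054,1702,0.070,0.046,7.30,0.311
auburn,Auburn,town,4,43,15901,NA,612,NA,2.238,6.29,5,4,20,500,1379,0.300,0.207,7.56,0.259
douglas,Douglas,town,4,34,7045,NA,494,NA,0.240,6.81,3,4,4,798,2319,0.040,0.043,7.62,0.215
millbury,Millbury,town,4,44,12784,NA,539,NA,1.884,5.53,5,3,13,573,1523,0.240,0.186,7.66,0.340
sutton,Sutton,town,4,35,8250,43980,391,2036,0.315,6.27,3,4,6,624,3090,0.040,0.036,7.40,0.224
blackstone,Blackstone,town,5,37,8804,NA,418,NA,1.335,5.82,4,3,6,749,3372,0.240,0.207,7.39,0.363
mendon,Mendon,town,5,38,5286,NA,224,NA,0.347,6.84,3,4,3,1044,2640,0.050,0.021,7.58,0.106
millville,Millville,town,5,39,2724,NA,177,NA,0.590,6.57,4,4,3,607,1187,0.100,0.067,7.53,0.201
northbridge,Northbridge,town,5,46,13182,NA,757,NA,0.717,5.72,4,3,9,465,2934,0.110,0.092,7.42,0.112
uxbridge,Uxbridge,town,5,36,11156,41152,625,2202,0.682,6.02,4,3,7,654,2610,0.090,0.065,7.54,0.328
dudley,Dudley,town,6,31,10036,NA,465,NA,0.957,5.85,4,3,7,877,2043,0.140,0.171,7.38,0.194
southbridge,Southbridge,town,6,32,17214,NA,971,NA,3.581,4.98,5,2,17,556,1833,0.530,0.595,6.43,0.829
webster,Webster,town,6,33,16415,43665,840,2275,5.602,2.42,5,1,13,525,2754,0.680,0.907,7.06,0.403
hopedale,Hopedale,town,7,41,5907,NA,304,NA,1.967,4.78,5,2,3,1524,2709,0.240,0.174,7.60,0.137
milford,Milford,town,7,42,26799,NA,1450,NA,4.183,4.27,5,2,19,663,2863,0.610,0.482,6.89,0.428
upton,Upton,town,7,40,5642,38348,330,2084,0.312,6.68,3,4,4,644,1812,0.060,0.042,7.55,0.183
grafton,Grafton,town,8,45,14894,NA,909,NA,1.062,5.97,4,3,10,324,4332,0.140,0.113,6.76,1.951
southborough,Southborough,town,8,48,8781,NA,415,NA,1.091,6.44,4,4,6,796,2742,0.140,0.079,7.32,0.257
westborough,Westborough,town,8,49,17997,41672,834,2158,2.162,5.74,5,3,12,616,3100,0.280,0.247,6.70,0.667
worcester_s9,Worcester (stratum 9),city_subdivision,9,51,NA,29690,2075,2075,NA,NA,4,3,29,488,2367,1.599,0.869,5.98,0.954
worcester_s10,Worcester (stratum 10),city_subdivision,10,51,NA,32800,2155,2155,NA,NA,5,2,36,415,1743,1.970,0.982,4.84,1.144
worcester_s11,Worcester (stratum 11),city_subdivision,11,51,NA,37984,2041,2041,NA,NA,3,4,30,424,3305,0.526,0.355,6.78,0.618
worcester_s12,Worcester (stratum 12),city_subdivision,12,51,NA,35627,2096,2096,NA,NA,4,3,40,514,2123,1.652,1.311,5.69,1.145
worcester_s13,Worcester (stratum 13),city_subdivision,13,51,NA,36547,2018,2018,NA,NA,4,4,32,428,3538,0.592,0.311,6.63,0.919
northborough,Northborough,town,14,47,14013,NA,607,NA,1.384,6.58,4,4,9,787,2766,0.190,0.124,7.25,0.259
shrewsbury,Shrewsbury,town,14,50,31640,45653,1698,2305,2.349,6.57,5,4,19,543,3150,0.330,0.238,6.90,0.588
berlin,Berlin,town,15,52,2380,NA,91,NA,0.353,6.80,3,4,3,394,1294,0.040,0.017,7.63,0.236
bolton,Bolton,town,15,53,4148,NA,245,NA,0.260,5.76,3,3,2,1831,2317,0.040,0.007,7.33,0.156
boylston,Boylston,town,15,54,4008,NA,175,NA,0.423,7.20,3,5,4,603,1787,0.070,0.066,7.34,0.220
clinton,Clinton,town,15,55,13435,NA,739,NA,3.659,3.93,5,2,9,856,3904,0.540,0.393,6.89,0.633
harvard,Harvard,town,15,56,5981,NA,156,NA,0.264,5.91,3,3,6,734,1202,0.040,0.019,6.89,0.748
lancaster,Lancaster,town,15,57,7380,NA,251,NA,0.577,6.81,4,4,4,720,2966,0.080,0.064,7.06,0.245
lunenburg,Lunenburg,town,15,58,9401,46733,353,2010,0.373,6.18,3,4,6,1109,2208,0.060,0.033,7.26,0.260
leominster,Leominster,town,16,59,41303,41303,2037,2037,3.115,4.53,5,2,25,608,3330,0.470,0.297,6.74,0.791
fitchburg,Fitchburg,town,17,60,39102,39102,2181,2181,5.021,2.54,5,1,34,104,2207,0.720,0.732,6.40,0.849
ashburnham,Ashburnham,town,18,6,5546,NA,254,NA,0.159,6.11,3,4,5,788,1843,0.030,0.021,7.53,0.240
brookfield,Brookfield,town,18,21,3051,NA,125,NA,0.234,5.86,3,3,3,929,1162,0.030,0.027,7.79,0.162
hardwick,Hardwick,town,18,7,2622,NA,100,NA,0.385,6.59,3,4,2,900,1722,0.050,0.064,7.50,0.297
hubbardston,Hubbardston,town,18,8,3909,NA,198,NA,0.060,7.00,2,5,2,1310,2599,0.010,0.000,7.61,0.021
new_braintree,New Braintree,town,18,9,927,NA,39,NA,0.015,7.94,2,4,1,927,927,0.015,0.000,7.94,0.000
petersham,Petersham,town,18,11,1180,NA,37,NA,0.000,7.02,1,5,1,1180,1180,0.000,0.000,7.02,0.000
phillipston,Phillipston,town,18,12,1621,NA,62,NA,0.035,7.71,2,4,1,1621,1621,0.035,0.000,7.71,0.000
princeton,Princeton,town,18,13,3353,NA,102,NA,0.055,6.17,2,4,2,1371,1982,0.010,0.007,7.21,0.120
sterling,Sterling,town,18,14,7257,NA,319,NA,0.182,6.96,3,5,3,1420,3092,0.030,0.010,7.41,0.189
templeton,Templeton,town,18,4,6799,NA,255,NA,0.297,5.30,3,3,6,502,1930,0.040,0.025,7.51,0.123
warren,Warren,town,18,26,4776,NA,96,NA,0.257,5.32,3,3,4,1025,1450,0.040,0.013,7.50,0.090
w_brookfield,W. Brookfield,town,18,27,3804,NA,138,NA,0.346,6.80,3,4,3,1114,1567,0.050,0.045,7.48,0.323
westminster,Westminster,town,18,15,6907,51752,263,1988,0.245,6.93,3,5,5,741,1789,0.030,0.016,7.33,0.251
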