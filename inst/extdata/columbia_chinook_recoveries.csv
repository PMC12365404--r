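hatchery,donor_home,donor_stray,donor_ambiguous,donor_total,donor_pct_mean,donor_pct_sd,recipient_home,recipient_stray,recipient_ambiguous,recipient_total,recipient_pct_mean,recipient_pct_sd,distance_km
Fallert Cr. Hatchery,10663,546,0,11209,5.3,6.0,8260,342,0,8602,9.03,15.7,97
Lewis River Hatchery,14581,271,33,14885,2.5,2.5,4190,103,23,4316,0.21,0.2,121
Cowlitz Salmon Hatch,61753,974,162,62889,0.2,0.4,50579,733,152,51464,4.31,4.4,136
Clackamas Hatchery,108512,4578,501,113591,1.0,1.7,86633,1441,307,88381,0.66,0.7,186
Little White Salmon NFH,230888,15998,21,246907,2.5,2.8,117268,22161,20,139449,17.20,12.2,229
Carson NFH,78232,13911,18,92161,17.3,15.2,58725,131,9,58865,0.31,0.7,235
Klickitat Hatchery,26370,598,0,26968,7.8,25.6,7484,74,0,7558,1.13,2.5,306
South Santiam Hatchery,51499,1781,552,53832,7.8,11.9,44277,112,221,44610,0.20,0.4,346
Marion Forks Hatchery,46821,1854,330,49005,1.7,4.0,24471,104,323,24898,6.06,13.3,386
Willamette Hatchery,60735,13142,18,73895,8.8,14.3,51342,363,11,51716,2.50,5.7,403
McKenzie Hatchery,71998,2088,62,74148,1.2,1.2,55514,3019,62,58595,6.04,13.0,409
Round Butte Hatchery,26868,87,425,27380,0.6,1.4,7009,304,43,7356,5.36,8.5,433
Entiat NFH,15296,569,0,15865,5.7,14.7,13150,1182,0,14332,1.64,2.4,715
Leavenworth Hatchery,79972,2012,9,81993,0.9,1.1,67014,408,2,67424,0.35,0.5,718
Dworshak Nat. Hatchery,38788,2910,500,42198,16.9,31.4,31350,994,457,32801,4.22,5.6,725
Kooskia NFH,15854,2354,58,18266,24.5,36.3,11904,666,28,12598,5.36,7.3,775
Winthrop NFH,16441,798,35,17274,8.6,22.2,17255,50,33,17338,3.57,12.9,823
Methow Hatchery,9147,730,2,9879,0.8,0.9,3696,6,2,3704,2.10,7.1,825
Lookingglass Hatchery,30620,3401,25,34046,5.7,5.7,1979,18,2,1999,0.82,1.6,828
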