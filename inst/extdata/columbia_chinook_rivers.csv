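hatchery,river,area_km2,isolation_km,distance_km,flow_mean,flow_sd,local_temp_mean,local_temp_sd,confluence_temp_mean,confluence_temp_sd,escapement_mean,escapement_sd
Fallert Cr. Hatchery,Kalama,463,11,97,57.1,21.2,16.1,0.4,22.0,0.4,506,544
Lewis River Hatchery,Lewis,1245,18,121,40.9,11.0,14.3,0.4,16.6,0.4,406,344
Cowlitz Salmon Hatch,Cowlitz,6423,11,136,97.4,23.3,15.4,0.4,21.7,0.4,2206,1926
Clackamas Hatchery,Clackamas,2434,137,186,25.6,3.9,16.9,0.4,19.2,0.4,3822,1696
Little White Salmon NFH,Ltl. White Salmon,347,14,229,6.7,2.3,13.4,0.5,20.6,0.5,6062,2354
Carson NFH,Wind,582,14,235,6.8,1.3,11.1,0.4,14.9,0.4,2675,2360
Klickitat Hatchery,Klickitat,3359,28,306,26.4,7.4,12.4,0.6,21.7,0.6,332,264
South Santiam Hatchery,Santiam,1657,1,346,21.7,3.2,13.0,0.4,18.7,0.4,1930,1121
Marion Forks Hatchery,Santiam,1781,1,386,28.6,3.1,12.4,0.4,18.6,0.4,1561,778
Willamette Hatchery,MF Willamette,5257,1,403,81.2,11.8,11.2,0.4,17.9,0.4,2143,1372
McKenzie Hatchery,McKenzie,3462,1,409,37.5,11.6,13.8,0.4,17.9,0.4,2543,1612
Round Butte Hatchery,Deschutes,27195,15,433,111.8,8.9,12.1,0.4,19.3,0.4,578,240
Entiat NFH,Entiat,1085,63,715,6.4,3.5,16.4,0.7,17.3,0.7,670,615
Leavenworth Hatchery,Wenatchee,3369,24,718,35.7,23.5,14.9,0.7,18.4,0.7,2931,1891
Dworshak Nat. Hatchery,Clearwater,24967,52,725,353.2,97.8,8.4,0.6,14.9,0.6,1540,809
Kooskia NFH,MF Clearwater,3489,52,775,57.8,19.2,21.7,0.6,17.5,0.6,599,383
Winthrop NFH,Methow,4687,63,823,12.6,5.6,13.5,0.5,18.4,0.5,824,873
Methow Hatchery,Methow,4687,63,825,11.8,5.5,19.8,0.6,18.4,0.6,246,208
Lookingglass Hatchery,Grand Ronde,3626,100,1282,18.1,6.6,11.1,0.6,21.8,0.6,245,342
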