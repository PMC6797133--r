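record_id,size,elevation,years_since,group,extinct
D00001,3,498.468570603989,1,oregon,0
D00002,20,798.218906568363,6,oregon,0
D00003,8,1203.54683803953,21,california,0
D00004,11,660.392634923104,47,oregon,0
D00005,18,847.807612394914,7,california,0
D00006,25,898.371265943628,7,oregon,0
D00007,43,1540.55337437056,7,california,0
D00008,16,263.383113592397,4,oregon,0
D00009,233,1756.48353132419,73,california,0
D00010,28,1400.90696440078,3,california,0
D00011,60,1438.83604519069,28,california,0
D00012,17,1199.93557323702,58,california,0
D00013,2,1657.1843789313,8,california,0
D00014,3,1284.43306367099,17,california,0
D00015,3,1033.3710350804,6,oregon,0
D00016,7,679.644834544975,28,oregon,0
D00017,1,992.968252899125,3,california,0
D00018,3,396.060425521806,14,oregon,0
D00019,9,315.514352981001,11,oregon,0
D00020,1,1004.23385951389,10,oregon,0
D00021,9,898.031858886592,3,oregon,0
D00022,1,1015.74147193553,16,oregon,0
D00023,4,497.323301719502,11,oregon,0
D00024,5,400.427902336698,7,oregon,0
D00025,4,402.309770760592,9,oregon,0
D00026,1,1235.60529829934,14,oregon,0
D00027,2,1568.38219289295,4,california,0
D00028,161,1845.08155340701,26,california,0
D00029,2,670.239109494258,2,oregon,0
D00030,15,857.515916186851,6,oregon,0
D00031,4,520.102339669131,11,oregon,0
D00032,9,374.737630849704,6,oregon,0
D00033,86,1383.71782780066,4,california,0
D00034,6,998.125476451591,2,oregon,0
D00035,3,455.026010621805,5,oregon,0
D00036,57,1234.37067710422,29,california,0
D00037,5,1829.88891987503,8,california,0
D00038,6,556.306564719416,4,oregon,0
D00039,4,629.618091580458,7,oregon,0
D00040,16,610.439848253038,3,oregon,0
D00041,10,1276.20472071506,5,oregon,0
D00042,1,861.218662338331,5,california,0
D00043,33,825.44178356044,14,california,0
D00044,9,329.80603164807,9,oregon,0
D00045,2,627.349511941895,42,oregon,0
D00046,11,1020.75500160642,40,california,0
D00047,46,1080.87692831829,8,oregon,0
D00048,3,1020.8663298022,21,california,0
D00049,2,1420.26272397675,10,california,0
D00050,150,1670.78178165667,3,california,0
D00051,6,968.679207248613,28,california,0
D00052,2,862.133887676988,8,oregon,0
D00053,19,868.140887981281,4,california,0
D00054,51,1148.55588129163,4,oregon,0
D00055,7,1727.24884447083,7,california,0
D00056,3,762.040388716385,20,oregon,0
D00057,16,1045.38194080442,8,california,0
D00058,10,1277.98566093855,10,oregon,0
D00059,7,377.270535605028,2,oregon,0
D00060,2,260.683995127212,45,oregon,0
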