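patient_id,shock_type,day,tewl_forehead,tewl_upper_limb,tewl_lower_limb,tewl_trunk,weight_kg,height_cm,core_temp_c,ventilated,svri,parenteral_ml,enteral_ml,urine_ml,ultrafiltrate_ml
S01,septic,1,1.3980900580670563,2.111111943572711,4.567195927710112,4.408567415655671,81.09751663721238,190.5501520999902,37.19506789333849,TRUE,NA,3711.934128997024,316.75177465191314,863.8546781064476,0
S01,septic,2,2.2287653157684697,3.365429179894609,7.280795550518872,7.027917902388183,81.09751663721238,190.5501520999902,36.58574328089778,TRUE,NA,2211.853581573818,245.77993268268673,753.9190649341255,0
S01,septic,3,3.0532967014432724,4.610469187228061,9.974324744288817,9.627895049137202,81.09751663721238,190.5501520999902,37.249809258225696,TRUE,NA,4469.583647862908,126.12781477621985,0,558.5409224782943
S01,septic,4,3.96893430585599,5.993079321322354,12.965474215671032,12.515155482806142,81.09751663721238,190.5501520999902,38.372578157143224,TRUE,NA,4364.4764988763645,585.747393388907,0,533.8876260521159
S02,septic,1,10.174810229078448,4.198517678999786,17.019355471572766,21.440111240605667,82.70978729638834,169.409781280124,37.65340617144466,TRUE,1351.4463400573295,5853.6215137504405,0,2615.5660941899823,1170.0890561078809
S02,septic,2,9.05219130363382,3.735281972471439,15.141556267352362,19.074556099974608,82.70978729638834,169.409781280124,37.826437563935464,TRUE,1403.9440773609274,2523.9145224968643,25.064877198543172,0,1104.2515854879557
S02,septic,3,7.595114613931288,3.134036140495991,12.704311191221247,16.004239739278688,82.70978729638834,169.409781280124,38.48053452387852,TRUE,828.4966530172684,4357.269803044413,0,206.78226358135169,0
S02,septic,4,11.95496754394724,4.933078991653805,19.997015934515524,25.191215192155397,82.70978729638834,169.409781280124,36.62653785674017,TRUE,1211.7510051351032,3838.516995163745,122.44825453731231,1792.3860961503228,426.19798645668953
S02,septic,5,9.102998481342349,3.756246966316701,15.226541185838364,19.181615742107187,82.70978729638834,169.409781280124,39.0172387590029,TRUE,2063.1270551187654,4985.64292866544,469.29315139568723,0,456.6935238869707
S03,septic,1,6.262804979254786,20.35512485859433,5.193362786942056,5.1742851548976425,59.59226541857982,171.7337281585843,39.06675471427651,TRUE,1465.98893208294,4291.523025745547,481.7150175442316,976.1066372609525,1137.4477421297217
S03,septic,2,9.468771758602246,30.775033238671043,7.8518758051802084,7.823032220856328,59.59226541857982,171.7337281585843,35.72557937389627,TRUE,1176.7786021308782,4490.380713285187,432.1249499458777,1318.9771827065751,835.6281734141605
S03,septic,3,8.787730600507382,28.561539787608456,7.287129845735269,7.260360835450382,59.59226541857982,171.7337281585843,37.74676294101928,TRUE,1387.4526056115296,4937.080093868656,0,643.8133783621685,959.029110788365
S04,septic,1,15.08436622708689,14.622569616609574,12.802119897032412,0.7654906928018111,110.05947422068476,181.95356801707842,36.98695703078267,TRUE,1595.5376027382733,5838.310994481114,123.63311931934322,1838.6604331891936,0
S04,septic,2,9.989356925643374,9.683540221138639,8.477979328471582,0.5069327831569139,110.05947422068476,181.95356801707842,37.261447755233185,TRUE,1591.800376630344,5069.51080042871,0,0,0
S04,septic,3,15.783877729669312,15.300666096776109,13.395796156982437,0.8009890052050934,110.05947422068476,181.95356801707842,36.656180391745444,TRUE,1473.0336007437409,5437.883576251078,0,810.5290413634457,0
S05,septic,1,1.2676618886345559,3.3739922403631355,3.430231652562083,4.253138532442397,96.5491379817682,194.6189055942116,37.80003269756592,TRUE,1811.3041062080226,4843.433649701799,414.26492060379906,80.75796706616063,1136.879987042248
S05,septic,2,3.099312236079486,8.24908875840574,8.386588749484483,10.398517470252624,96.5491379817682,194.6189055942116,37.732420702930526,TRUE,688.8975669267257,3727.380420273131,0,554.0766795871418,289.44080578469135
S05,septic,3,2.4021016538620232,6.393402226064992,6.499970693782225,8.059302874435001,96.5491379817682,194.6189055942116,37.24784078158051,TRUE,1127.9874106513703,4565.933824191365,0,966.6622108008751,702.8963357928785
S05,septic,4,2.1488354970473345,5.71931234807727,5.814644744159907,7.209568367016454,96.5491379817682,194.6189055942116,37.470388900523204,TRUE,1512.0073942597887,5082.550110954981,153.6046392910108,373.7767380488547,453.7877496777501
S05,septic,5,1.8052069101113712,4.804715012396759,4.884802436679504,6.056658433342964,96.5491379817682,194.6189055942116,36.62753364684286,TRUE,1621.5556529873359,3654.023059072339,108.90146784011866,1600.131024201486,700.9892561605211
S05,septic,6,2.7337559472892194,7.276128939346395,7.397411143181146,9.172037798054534,96.5491379817682,194.6189055942116,37.8213430709788,TRUE,870.5863473087514,4868.157610329918,179.38200515699432,1131.781474068548,0
C01,cardiogenic,1,11.679592133600492,9.047656854788324,9.470679945108216,4.075420262452589,82.30368337749175,187.8271788029805,37.36034628884519,TRUE,NA,3622.4371873434015,211.68209454677208,0,3194.617965480187
C01,cardiogenic,2,16.459367860712238,12.750335007165031,13.346476771150076,5.743252034780519,82.30368337749175,187.8271788029805,35.880441596404495,TRUE,NA,2239.7469124649897,0,3680.269918215962,0
C01,cardiogenic,3,9.710120172688981,7.521995146431963,7.873685941439388,3.388202263397627,82.30368337749175,187.8271788029805,37.47341753321958,TRUE,NA,3749.964182869082,617.3159701635209,110.94967640884477,2436.6880858620643
C02,cardiogenic,1,21.447952864523113,2.7323830025938607,4.821104621902991,3.0217077858952757,64.11084018811728,178.20008451911187,37.87098515632266,TRUE,3791.38718806237,1855.4028383820028,461.741000719977,4.481816875148411,1939.2795058754891
C02,cardiogenic,2,40.20617438471651,5.122105041075525,9.037607196340897,5.664471147748506,64.11084018811728,178.20008451911187,38.03630781971631,TRUE,1775.6546917941087,2367.3596119501426,779.2155664616299,92.51835990886138,1076.189366930707
C02,cardiogenic,3,16.14811426069386,2.0572048627935327,3.629798554155848,2.27503682506578,64.11084018811728,178.20008451911187,37.23270029066979,TRUE,3873.285212938792,2428.8891492048565,9.097367919934129,1052.4387021904224,2755.1222546979384
C02,cardiogenic,4,23.541866802548217,2.9991392235392103,5.291777894464027,3.3167101149982487,64.11084018811728,178.20008451911187,37.01036595139519,TRUE,3247.2256685828916,3963.2439947329913,395.13769932936844,0,0
C03,cardiogenic,1,39.752564632320855,2.6966575283134495,10.38124973773281,5.064419634224252,100.68017248613435,174.3292546759543,36.441907355228516,TRUE,2892.6136833300347,3492.715858153459,0,2804.5655530604363,1484.5066867801038
C03,cardiogenic,2,38.48563683052543,2.610714132556702,10.05039576562401,4.90301485206988,100.68017248613435,174.3292546759543,36.75383643952173,TRUE,2793.323414581944,1802.7031086924935,504.7981366677439,0,0
C03,cardiogenic,3,31.26722015370303,2.1210451551184524,8.165330313213381,3.9833989358583164,100.68017248613435,174.3292546759543,38.582014325253276,TRUE,3013.6675921835376,2234.500738110987,1175.8961019966973,213.6980027083041,0
C03,cardiogenic,4,28.00673483698098,1.8998666637024468,7.31386544164677,3.56801778981569,100.68017248613435,174.3292546759543,37.64208655672485,TRUE,2969.971112792746,4140.265820959503,306.2779451354523,3325.424563702083,1828.5391991726012
C03,cardiogenic,5,37.433681314197976,2.539353610567918,9.775681089250604,4.768997230301455,100.68017248613435,174.3292546759543,37.62873992843401,TRUE,2769.6205931194595,4141.198506124464,266.56278749598283,0,215.76215628145246
C03,cardiogenic,6,23.524929153429458,1.5958386054181073,6.143456827579388,2.9970421833235803,100.68017248613435,174.3292546759543,37.668214687071284,TRUE,3494.1371345076623,2238.383041681128,1287.6443506603534,1366.5007104370784,1390.6868157516226
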