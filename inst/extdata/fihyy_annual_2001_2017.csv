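year,NEE_TS,NEE_SP,GPP_TS,GPP_TA,RE_TS,RE_TA,ET,TA,TS,D,PAR,CA,GS_START,GS_END,GS_LENGTH,SCU,ECU,CUP,NEP_GAPS,NEE_TS_MS,GPP_TS_MS,GPP_TA_MS,RE_TS_MS,RE_TA_MS,ET_MS,LUE_MS,WUE_MS,TA_MS,TS_MS,D_MS,PAR_MS,P_MS,GS_MS
2001,180,165,1013,1044,833,865,356,3.9,5.3,0.25,200.4,374.7,118,298,180,101,254,153,33.9,280,903,936,623,656,305,15.89,4.44,12.9,9.7,0.72,353.8,389,0.20
2002,236,209,1069,1105,833,869,345,4.3,6.7,0.31,220.9,374.8,116,268,152,104,292,188,35.8,307,953,989,646,682,298,15.18,4.71,14.2,11.1,0.81,384.5,282,0.17
2003,171,137,1158,1183,986,1011,325,4.1,5.9,0.25,199.7,376.2,130,291,161,110,239,129,41.8,268,1044,1070,776,802,288,18,5.12,13.4,10.3,0.67,340.7,304,0.20
2004,221,210,1117,1148,896,927,302,4.0,5.1,0.27,194.9,378.4,112,289,177,106,247,142,31.9,270,966,995,696,725,255,19.14,5.61,12.2,9.8,0.69,312.6,411,0.19
2005,238,216,1146,1182,908,943,296,4.5,5.6,0.30,215.6,378.6,129,301,172,97,269,172,26.7,288,1007,1041,719,753,250,17.09,5.97,12.9,10.2,0.84,363.3,414,0.15
2006,204,186,1040,1078,836,874,330,4.8,5.6,0.33,223.9,379.6,119,307,188,108,273,165,31.0,320,927,963,607,643,261,14.4,5.33,14.3,10.3,0.95,400.6,210,0.13
2007,239,236,1171,1203,932,964,377,4.7,5.8,0.26,209.7,386.9,89,288,199,82,268,186,29.8,305,1002,1036,696,730,289,17.24,5.22,12.8,10.5,0.76,359.9,319,0.18
2008,249,239,1070,1106,821,857,366,4.9,5.5,0.23,185.0,387.4,120,308,188,97,270,173,25.2,325,923,956,598,631,263,17.49,5.35,11.5,9.8,0.7,330.2,482,0.18
2009,312,305,1228,1268,915,956,372,3.8,5.1,0.26,200.7,391.6,119,287,168,102,289,187,33.4,394,1106,1146,712,752,303,19.05,5.44,13.0,10.2,0.77,355.9,325,0.19
2010,240,227,1135,1169,895,929,394,2.5,5.4,0.28,197.7,393.5,137,290,153,101,257,157,41.5,294,1014,1051,721,757,328,17.84,4.66,13.9,11.0,0.9,350.3,437,0.18
2011,288,287,1257,1288,968,1000,340,5.2,6.0,0.28,197.5,395.3,117,319,202,105,256,152,34.7,379,1095,1129,716,750,276,19.73,5.83,14.0,11.2,0.87,340.0,479,0.16
2012,268,272,1180,1209,912,941,330,3.2,5.5,0.20,186.7,398.6,133,300,167,111,267,156,35.5,348,1064,1097,716,749,268,20.21,6,12.2,10.3,0.68,327.8,482,0.20
2013,273,268,1249,1273,975,999,352,5.1,5.9,0.26,203.0,400.1,132,295,163,112,266,154,37.4,379,1119,1145,740,766,294,19.62,5.58,14.1,11.2,0.79,347.7,318,0.18
2014,287,274,1167,1206,880,919,357,5.2,6.0,0.28,195.1,401.5,120,294,174,67,272,205,29.3,329,996,1031,667,702,299,18.08,4.93,13.6,11.2,0.88,340.5,410,0.17
2015,306,297,1166,1199,861,893,368,5.7,6.2,0.23,192.2,403.5,127,284,157,91,267,177,27.2,355,982,1014,627,659,289,17.81,5.07,12.5,10.5,0.7,343.3,334,0.20
2016,285,270,1224,1258,939,973,371,4.5,5.7,0.23,187.8,406.8,124,288,164,90,278,189,45.3,324,1064,1094,740,770,291,19.42,5.47,13.7,11.2,0.72,335.2,496,0.20
2017,284,274,1122,1148,838,864,337,4.3,5.1,0.19,202.7,409.5,142,297,155,78,262,183,31.5,353,965,993,611,640,241,16.88,5.99,11.4,9.2,0.61,355.9,425,0.18
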