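patient,net_gadoteridol,net_gadobutrol,net_difference,avg_gadoteridol,avg_gadobutrol,avg_difference,first_agent
1,2660.6,2355.5,305.1,0.096,0.085,0.011,NA
2,225.3,196.1,29.1,0.040,0.034,0.005,NA
3,7421.5,6814.4,607.1,0.139,0.128,0.011,NA
4,1829.6,1533.0,296.6,0.113,0.095,0.018,NA
5,736.3,949.3,-213.0,0.163,0.210,-0.047,NA
6,1836.3,1635.1,201.1,0.211,0.188,0.023,NA
7,2306.0,2816.1,-510.1,0.130,0.159,-0.029,NA
8,711.3,695.5,15.8,0.176,0.172,0.004,gadoteridol
9,2445.9,2225.5,220.4,0.093,0.084,0.008,NA
10,3755.9,3356.3,399.6,0.380,0.339,0.040,NA
11,9759.5,9814.0,-54.5,0.217,0.218,-0.001,NA
12,596.4,534.8,61.6,0.089,0.079,0.009,NA
13,2326.9,2505.6,-178.7,0.184,0.198,-0.014,NA
14,308.1,317.2,-9.1,0.065,0.067,-0.002,NA
15,1255.6,1082.3,173.3,0.102,0.088,0.014,NA
16,280.5,226.9,53.6,0.039,0.031,0.007,NA
17,2353.9,2640.1,-286.2,0.182,0.205,-0.022,NA
18,277.3,248.1,29.2,0.187,0.167,0.020,NA
19,364.5,304.8,59.8,0.072,0.060,0.012,NA
20,13009.7,15861.3,-2851.6,0.159,0.194,-0.035,NA
21,142.0,129.9,12.1,0.107,0.098,0.009,NA
22,1247.2,873.2,374.0,0.172,0.120,0.052,NA
23,2119.5,2103.0,16.6,0.190,0.189,0.001,gadobutrol
24,230.1,164.5,65.6,0.041,0.029,0.012,NA
25,1339.9,1539.6,-199.7,0.148,0.170,-0.022,NA
26,1453.5,1402.2,51.3,0.060,0.058,0.002,NA
27,1307.5,634.4,673.1,0.057,0.028,0.029,NA
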