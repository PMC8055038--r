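item,province,prevalence,missing_rate,beta,alpha,starred
education,QC,0.7557,0.0049,1.1751,1.0688,1
education,ON,0.625,0.0024,0.7735,0.4028,1
education,BC,0.7246,0.0195,1.4017,1.0274,1
education,SK,0.9133,0.0051,0.5528,1.5553,1
vulnerable_housing,QC,0.1783,0.0212,1.1731,-1.4208,0
vulnerable_housing,ON,0.044,0,1.3095,-2.8108,0
vulnerable_housing,BC,0.1059,0.0107,1.5974,-2.3529,0
vulnerable_housing,SK,0.0863,0,0.6106,-1.5981,0
living_alone,QC,0.5983,0.0212,0.7753,0.3151,0
living_alone,ON,0.489,0,0.6286,-0.0326,0
living_alone,BC,0.6032,0.0107,0.9552,0.3619,0
living_alone,SK,0.3503,0,1.2033,-0.6018,0
low_income,QC,0.8369,0.0098,0.8562,1.2925,1
low_income,ON,0.6559,0.0122,0.8924,0.538,1
low_income,BC,0.7676,0.0142,1.1337,1.1048,1
low_income,SK,0.8449,0.0508,0.8095,1.3057,1
not_married,QC,0.8725,0.0277,0.6625,1.3653,0
not_married,ON,0.7604,0,1.0924,1.0479,0
not_married,BC,0.7953,0.0195,0.9636,1.1456,0
not_married,SK,0.736,0,1.2547,1.0127,0
unemployed,QC,0.7941,0.0016,1.1621,1.2584,1
unemployed,ON,0.7819,0.0024,1.3377,1.3002,1
unemployed,BC,0.8,0.0142,0.8993,1.1319,1
unemployed,SK,0.8265,0.0051,1.2364,1.4956,1
non_gbmsm,QC,0.7512,0.0098,0.5675,0.78,1
non_gbmsm,ON,0.6225,0.0024,1.2322,0.4954,1
non_gbmsm,BC,0.812,0.0266,0.6902,1.0759,1
non_gbmsm,SK,0.9645,0,1.2733,2.9225,1
indigenous,QC,0.0282,0.0179,1.0213,-2.7262,1
indigenous,ON,0.1495,0.0024,0.8858,-1.3874,1
indigenous,BC,0.3369,0.0089,1.0776,-0.6188,1
indigenous,SK,0.8163,0.0051,1.7172,1.7913,1
incarceration,QC,0.665,0.031,1.1628,0.6535,1
incarceration,ON,0.5452,0.0807,0.6648,0.1364,1
incarceration,BC,0.7157,0.1314,0.6285,0.6735,1
incarceration,SK,0.8272,0.0305,0.8171,1.2181,1
idu_ever,QC,0.8216,0.0033,1.1383,1.3962,1
idu_ever,ON,0.6822,0,1.2205,0.7475,1
idu_ever,BC,0.8689,0.0107,0.7341,1.3911,1
idu_ever,SK,0.9239,0,1.124,2.1536,1
idu_6mo,QC,0.3668,0.0082,0.6886,-0.4133,1
idu_6mo,ON,0.2372,0,1.2315,-1.135,1
idu_6mo,BC,0.4263,0.0124,0.7979,-0.2378,1
idu_6mo,SK,0.5431,0,0.6992,0.1322,1
snort_6mo,QC,0.2441,0.0375,0.8472,-0.9086,0
snort_6mo,ON,0.1802,0.0367,0.7585,-1.1479,0
snort_6mo,BC,0.1959,0.0568,0.9409,-1.176,0
snort_6mo,SK,0.1813,0.0203,0.9183,-1.2358,0
sex_client_ever,QC,0.303,0.0147,0.803,-0.6616,0
sex_client_ever,ON,0.2321,0.0098,1.1281,-1.1034,0
sex_client_ever,BC,0.2477,0.0249,0.6362,-0.8079,0
sex_client_ever,SK,0.1168,0,0.6576,-1.4259,0
sex_work_ever,QC,0.3107,0.0131,0.8049,-0.6338,0
sex_work_ever,ON,0.1961,0.0024,0.9523,-1.1817,0
sex_work_ever,BC,0.3852,0.0178,1.256,-0.4687,0
sex_work_ever,SK,0.2335,0,1.2932,-1.189,0
sex_work_6mo,QC,0.0681,0.0179,1.0922,-2.2065,0
sex_work_6mo,ON,0.0223,0.0122,1.7201,-3.9969,0
sex_work_6mo,BC,0.0722,0.0409,0.7528,-1.8268,0
sex_work_6mo,SK,0.078,0.2843,0.8152,-1.8302,0
depression,QC,0.3154,0.0016,1.2275,-0.7611,0
depression,ON,0.5844,0,0.9843,0.2989,0
depression,BC,0.6007,0.0036,1.3752,0.4339,0
depression,SK,0.5533,0,0.9005,0.1803,0
psych_hosp,QC,0.2142,0.0326,0.6633,-0.9505,1
psych_hosp,ON,0.2421,0,1.0411,-1.0101,1
psych_hosp,BC,0.2685,0.0142,0.746,-0.7703,1
psych_hosp,SK,0.2183,0,0.7373,-0.9666,1
schizophrenia,QC,0.0414,0.1321,1.0551,-2.5224,0
schizophrenia,ON,0.0172,0.0073,1.2046,-3.3102,0
schizophrenia,BC,0.0254,0.0213,1.037,-2.8136,0
schizophrenia,SK,0.0663,0.0051,1.3068,-2.4744,0
sti_6mo,QC,0.0565,0.0179,0.8163,-2.0461,0
sti_6mo,ON,0.0866,0.0122,0.9885,-1.9148,0
sti_6mo,BC,0.0789,0.032,1.1994,-2.2058,0
sti_6mo,SK,0.0263,0.0355,0.9336,-2.6512,0
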