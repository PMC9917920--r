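week_start,new_cases,emergency_declared
2020-01-06,0,false
2020-01-13,0,false
2020-01-20,0,false
2020-01-27,0,false
2020-02-03,9,false
2020-02-10,30,false
2020-02-17,84,false
2020-02-24,203,false
2020-03-02,417,false
2020-03-09,730,false
2020-03-16,1089,false
2020-03-23,1385,false
2020-03-30,1500,false
2020-04-06,1385,true
2020-04-13,1090,true
2020-04-20,731,true
2020-04-27,421,true
2020-05-04,214,true
2020-05-11,113,true
2020-05-18,97,true
2020-05-25,156,false
2020-06-01,296,false
2020-06-08,542,false
2020-06-15,920,false
2020-06-22,1442,false
2020-06-29,2082,false
2020-07-06,2770,false
2020-07-13,3397,false
2020-07-20,3840,false
2020-07-27,4000,false
2020-08-03,3840,false
2020-08-10,3397,false
2020-08-17,2770,false
2020-08-24,2082,false
2020-08-31,1442,false
2020-09-07,920,false
2020-09-14,541,false
2020-09-21,293,false
2020-09-28,147,false
2020-10-05,68,false
2020-10-12,29,false
2020-10-19,11,false
2020-10-26,0,false
2020-11-02,0,false
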