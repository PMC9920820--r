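dataset,description,algorithm,tp,fp,fn,tb,failed_detection,error_rate_pct,error_rate_consistent
A1,High Quality,pt,72073,191,348,72415,539,0.74,TRUE
A1,High Quality,ampt,72267,135,148,72415,283,0.39,TRUE
A2,Low Quality,pt,64653,11137,14065,78618,25202,32.06,TRUE
A2,Low Quality,ampt,64993,8671,13639,78618,22310,28.38,TRUE
B1,Normal Sinus Rhythm,pt,45231,134,2988,48494,3122,6.44,TRUE
B1,Normal Sinus Rhythm,ampt,45301,8,3083,48494,3091,6.37,TRUE
B2,Arrhythmias,pt,99783,349,3720,103724,4069,3.92,TRUE
B2,Arrhythmias,ampt,100135,144,3380,103724,3524,3.40,TRUE
C,Paced Rhythm,pt,6684,2132,2238,8923,4370,48.97,TRUE
C,Paced Rhythm,ampt,8468,276,454,8923,730,8.18,TRUE
D,TeleHealth,pt,3218,972,522,6708,1494,40.10,FALSE
D,TeleHealth,ampt,3394,707,334,6708,1041,27.94,FALSE
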