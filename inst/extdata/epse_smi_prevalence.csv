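partition,stratum,cohort_size,dystonia,akathisia,parkinsonism,tardive_dyskinesia
age,Under 21,318,5.97,8.18,3.46,0.63
age,21 to 30,2106,4.51,6.03,2.71,1.47
age,31 to 40,3018,3.61,5.40,2.78,1.46
age,41 to 50,3249,2.65,6.25,2.22,2.28
age,51 to 60,2119,2.27,5.85,3.21,2.41
age,61 to 70,1129,1.86,5.93,6.20,5.23
age,71 to 80,677,1.33,4.73,9.31,7.39
age,Above 80,263,1.14,3.04,5.70,4.94
gender,Male,6969,3.49,6.50,3.26,2.55
gender,Female,5910,2.49,5.03,3.60,2.47
ethnicity,White,5788,2.32,6.10,3.27,2.16
ethnicity,Black,4682,4.44,5.55,3.55,3.25
ethnicity,Asians,861,2.32,8.13,6.04,3.14
ethnicity,Other,1548,1.81,4.33,2.13,1.29
diagnosis,Schizophreniform,8411,3.11,5.91,3.40,2.87
diagnosis,Bipolar,3208,2.03,3.99,2.77,1.00
diagnosis,Schizoaffective,1260,5.00,9.92,5.16,4.05
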