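age_months,sex,median_kg,lms_l,lms_s
0,male,3.3,-0.2,0.13
1,male,4.5,-0.2,0.13
2,male,5.6,-0.2,0.13
3,male,6.4,-0.2,0.13
4,male,7.0,-0.2,0.13
6,male,7.9,-0.2,0.13
9,male,8.9,-0.2,0.13
12,male,9.6,-0.2,0.13
18,male,10.9,-0.2,0.13
24,male,12.2,-0.2,0.13
36,male,14.3,-0.2,0.13
48,male,16.3,-0.2,0.13
60,male,18.3,-0.2,0.13
0,female,3.2,-0.2,0.14
1,female,4.2,-0.2,0.14
2,female,5.1,-0.2,0.14
3,female,5.8,-0.2,0.14
4,female,6.4,-0.2,0.14
6,female,7.3,-0.2,0.14
9,female,8.2,-0.2,0.14
12,female,8.9,-0.2,0.14
18,female,10.2,-0.2,0.14
24,female,11.5,-0.2,0.14
36,female,13.9,-0.2,0.14
48,female,16.1,-0.2,0.14
60,female,18.2,-0.2,0.14
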