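id,age,sex,mass_kg,activity_h_per_day,offset_mm,score,K,months_predicted,months_recorded
1,40,F,50,4,25.6,0.537,4.04,297.2,298
2,47,F,65,5,36.7,0.545,4.08,189.2,186
3,53,M,80,4,31.2,0.703,5.00,205.8,209
4,55,F,65,5,24,0.537,4.04,214.5,205
5,39,M,78,3.5,31.1,0.702,5.00,238.1,247
6,42,F,57,4.5,30.3,0.571,4.22,232.7,216
7,41,M,80,4,26.1,0.414,3.44,256.6,258
8,42,F,50,5.5,31.2,0.532,4.01,205.2,216
9,54,F,70,4,30,0.521,3.96,246.1,261
10,48,M,100,6,35.4,0.712,5.06,118.7,125
11,44,F,55,5,36.4,0.543,4.07,205,206
12,50,M,70,6,26.4,0.841,5.95,141.2,154
13,42,M,70,5,29.5,0.542,4.07,195.4,204
14,36,F,60,4,29.4,0.551,4.11,261.1,278
15,54,F,50,4,28.8,0.545,4.08,286.4,302
16,37,F,58,4,25.2,0.702,5.00,253,253
17,41,F,65,4,32.4,0.975,6.99,192,192
18,40,F,45,4,34.4,0.529,4.00,288,288
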