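"pulse_index","conductance_S"
0,0.00151715435371005
1,0.00202779292884133
2,0.00247418105277545
3,0.00284002928569766
4,0.00312837750791539
5,0.00337173458790777
6,0.00360140153062549
7,0.00374994942429231
8,0.00388972445845795
9,0.00404090960899942
10,0.00409495209035593
11,0.00421841178816808
12,0.0042709097207932
13,0.00427956878797059
14,0.00435446435506696
15,0.00435729294957246
16,0.00381750760371917
17,0.00340916188653158
18,0.00306974103923885
19,0.00280101964281625
20,0.00256627373912294
21,0.00237388838142043
22,0.00222417680902569
23,0.00206754399685511
24,0.00198981852493841
25,0.00189307393416835
26,0.00182774141364204
27,0.00176834831669452
28,0.0017073345385371
29,0.00167461505202297
30,0.00163791928764898
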