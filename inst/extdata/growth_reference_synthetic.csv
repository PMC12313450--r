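ga_week,p3_kg,p50_kg,p97_kg
24,0.448,0.64,0.858
25,0.518,0.74,0.992
26,0.602,0.86,1.152
27,0.693,0.99,1.327
28,0.791,1.13,1.514
29,0.903,1.29,1.729
30,1.022,1.46,1.956
31,1.155,1.65,2.211
32,1.351,1.85,2.424
33,1.504,2.06,2.699
34,1.672,2.29,3.000
35,1.840,2.52,3.301
36,2.015,2.76,3.616
37,2.272,2.99,3.797
38,2.432,3.20,4.064
39,2.569,3.38,4.293
40,2.675,3.52,4.470
41,2.759,3.63,4.610
42,2.812,3.70,4.699
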