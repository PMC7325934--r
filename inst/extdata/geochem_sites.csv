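site,moisture_pct,tc_g_kg,tn_g_kg,tp_mg_kg,loi_pct,nh4_mg_kg,no3_mg_kg,po4_mg_kg,thg_ng_g,mehg_ng_g
H-02,54.8,2.868,1.89,308,6.5,32.13,3.230,0.096,9.80,0.27
S1,69.0,5.997,4.469,1371,20.0,114.19,0.623,0.335,788.28,0.98
S3,50.5,4.156,2.245,242,8.0,4.99,0.250,b.d.,26.19,0.82
R1,32.8,1.219,0.628,68.5,2.4,29.67,b.d.,b.d.,13.64,0.27
B,31.8,0.951,0.852,495,4.3,61.81,0.550,0.027,1688.31,1.21
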