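subject,maneuver,J_aw_pl_s,D_aw_pl_s_ppb,J_A_pl_s,D_A_pl_s_ppb,C_ET_ppb,C_A_ppb,IFR_ml_s,EFR_ml_s,V_ml,etCO2_pct,C_amb_ppb,hold_s
1,A,220,1.6,2.05e7,8800,2020,2330,152,204,770,6.0,119,0
1,B,220,1.6,1.76e7,7400,2118,2378,121,121,726,5.9,130,0
1,C,220,1.6,1.65e7,7100,2201,2324,108,61,765,6.2,125,0
1,D,220,1.6,1.44e7,6100,2297,2360,209,151,1041,6.5,112,20
2,A,240,1.6,1.65e7,10000,1518,1650,241,217,1087,4.9,154,0
2,B,240,1.6,1.18e7,7250,1560,1628,122,103,1064,5.4,162,0
2,C,240,1.6,1.15e7,6700,1658,1716,52,54,1041,5.9,132,0
2,D,240,1.6,1.05e7,6100,1671,1721,114,106,1061,5.8,112,10
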