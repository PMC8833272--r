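patient,eud_ssvr_cGy,eud_lsvr_cGy,ntcp_ssvr_pct,ntcp_lsvr_pct
1,636,1128,0.00,0.10
2,708,931,0.00,0.02
3,497,1064,0.00,0.06
4,548,1087,0.00,0.07
5,259,600,0.00,0.00
6,407,806,0.00,0.01
7,99,281,0.00,0.00
8,484,1117,0.00,0.09
9,431,728,0.00,0.00
10,671,1359,0.00,0.44
11,752,1262,0.00,0.24
12,977,1641,0.03,1.94
13,426,990,0.00,0.03
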