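label,terminal,n,disulfides,metal1,metal2,adduct,expected_mz,decimals
(S-S)PyC2-Gly,Gly,2,1,,,M+H,538.1272,4
PyC2-Gly,Gly,2,0,,,M+H,540.1429,4
PyC3-Gly,Gly,3,0,,,M+H,772.1946,4
PyC4-Gly,Gly,4,0,,,M+H,1004.2464,4
PyC5-Gly,Gly,5,0,,,M+H,1236.2982,4
PyC6-Gly,Gly,6,0,,,M+H,1468.35,2
PyC2-Ser,Ser,2,0,,,M+H,570.1534,4
PyC3-Ser,Ser,3,0,,,M+H,802.2052,4
PyC4-Ser,Ser,4,0,,,M+H,1034.257,3
PyC2-Gln,Gln,2,0,,,M+H,611.18,2
PyC3-Gln,Gln,3,0,,,M+H,843.2318,4
PyC2-Glu,Glu,2,0,,,M+H,612.164,3
PyC3-Glu,Glu,3,0,,,M+H,844.2158,4
PyC4-Glu,Glu,4,0,,,M+H,1076.2675,4
PyC2-Gly-Hg,Gly,2,0,Hg,,M+H,740.0979,4
PyC3-Gly-Hg,Gly,3,0,Hg,,M+H,972.1496,4
(S-S)PyC4-Gly-Hg,Gly,4,1,Hg,,M+H,1202.1858,4
PyC4-Gly-Hg(2),Gly,4,0,Hg,Hg,M+H,1404.1564,4
PyC2-Gly-Cd,Gly,2,0,Cd,,M+H,652.0306,4
PyC3-Gly-Cd,Gly,3,0,Cd,,M+H,884.0824,4
PyC4-Gly-Cd,Gly,4,0,Cd,,M+H,1116.1341,4
PyC4-Gly-Cd(2),Gly,4,0,Cd,Cd,M+H,1228.0218,4
PyC5-Gly-Cd,Gly,5,0,Cd,,M+H,1348.1859,4
PyC2-Gly-Pb,Gly,2,0,Pb,,M+H,746.1039,4
PyC3-Gly-Pb,Gly,3,0,Pb,,M+H,978.1556,4
PyC4-Gly-Pb,Gly,4,0,Pb,,M+H,1210.2074,4
PyC4-Gly-Pb(2),Gly,4,0,Pb,Pb,M+H,1416.1684,4
PyC2-Gly-Zn,Gly,2,0,Zn,,M+H,602.0564,4
PyC3-Gly-Zn,Gly,3,0,Zn,,M+H,834.1081,4
PyC4-Gly-Zn,Gly,4,0,Zn,,M+H,1066.1599,4
PyC4-Gly-Zn(2),Gly,4,0,Zn,Zn,M+H,1128.0734,4
PyC2-Gly-Mn,Gly,2,0,Mn,,M+H,593.0653,4
PyC3-Gly-Mn,Gly,3,0,Mn,,M+H,825.117,4
PyC4-Gly-Mn,Gly,4,0,Mn,,M+H,1057.1688,4
PyC4-Gly-Mn(2),Gly,4,0,Mn,Mn,M+H,1110.0912,4
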