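group,rank,functional,family,hf_exchange,mue,maxe,complex_id,signed_error
A,1,BB1K,hm-GGA,42.00,0.67,1.76,Fe(H2O),-0.47
A,1,BB1K,hm-GGA,42.00,0.67,1.76,Fe(H2O)2,0.21
A,1,BB1K,hm-GGA,42.00,0.67,1.76,Fe(H2O)4,-0.26
A,1,BB1K,hm-GGA,42.00,0.67,1.76,Fe(H2O)6,1.76
A,2,mPWB1K,hm-GGA,44.00,0.99,1.93,Fe(H2O),0.44
A,2,mPWB1K,hm-GGA,44.00,0.99,1.93,Fe(H2O)2,1.28
A,2,mPWB1K,hm-GGA,44.00,0.99,1.93,Fe(H2O)4,0.29
A,2,mPWB1K,hm-GGA,44.00,0.99,1.93,Fe(H2O)6,1.93
A,3,mPW1N,h-GGA,40.60,2.23,3.49,Fe(H2O),1.21
A,3,mPW1N,h-GGA,40.60,2.23,3.49,Fe(H2O)2,2.55
A,3,mPW1N,h-GGA,40.60,2.23,3.49,Fe(H2O)4,1.68
A,3,mPW1N,h-GGA,40.60,2.23,3.49,Fe(H2O)6,3.49
A,4,BMK,hm-GGA,42.00,2.41,3.62,Fe(H2O),3.39
A,4,BMK,hm-GGA,42.00,2.41,3.62,Fe(H2O)2,1.52
A,4,BMK,hm-GGA,42.00,2.41,3.62,Fe(H2O)4,-1.10
A,4,BMK,hm-GGA,42.00,2.41,3.62,Fe(H2O)6,3.62
A,5,mPW1B95,hm-GGA,31.00,2.49,4.12,Fe(H2O),-2.39
A,5,mPW1B95,hm-GGA,31.00,2.49,4.12,Fe(H2O)2,-4.12
A,5,mPW1B95,hm-GGA,31.00,2.49,4.12,Fe(H2O)4,-2.56
A,5,mPW1B95,hm-GGA,31.00,2.49,4.12,Fe(H2O)6,0.89
A,6,M06-2X,hm-GGA,54.00,2.53,4.50,Fe(H2O),4.50
A,6,M06-2X,hm-GGA,54.00,2.53,4.50,Fe(H2O)2,3.79
A,6,M06-2X,hm-GGA,54.00,2.53,4.50,Fe(H2O)4,0.89
A,6,M06-2X,hm-GGA,54.00,2.53,4.50,Fe(H2O)6,0.93
A,7,mPW1K,h-GGA,42.80,2.62,3.51,Fe(H2O),1.70
A,7,mPW1K,h-GGA,42.80,2.62,3.51,Fe(H2O)2,3.30
A,7,mPW1K,h-GGA,42.80,2.62,3.51,Fe(H2O)4,1.98
A,7,mPW1K,h-GGA,42.80,2.62,3.51,Fe(H2O)6,3.51
A,8,MN12-SX,hm-NGA,25.00/-,2.98,7.43,Fe(H2O),0.81
A,8,MN12-SX,hm-NGA,25.00/-,2.98,7.43,Fe(H2O)2,-1.43
A,8,MN12-SX,hm-NGA,25.00/-,2.98,7.43,Fe(H2O)4,2.25
A,8,MN12-SX,hm-NGA,25.00/-,2.98,7.43,Fe(H2O)6,7.43
A,9,B3LYP,h-GGA,20.00,3.03,5.41,Fe(H2O),-0.67
A,9,B3LYP,h-GGA,20.00,3.03,5.41,Fe(H2O)2,-5.41
A,9,B3LYP,h-GGA,20.00,3.03,5.41,Fe(H2O)4,-2.61
A,9,B3LYP,h-GGA,20.00,3.03,5.41,Fe(H2O)6,3.42
A,10,mPW2PLYP,hh-GGA,55.00,3.08,4.69,Fe(H2O),-3.55
A,10,mPW2PLYP,hh-GGA,55.00,3.08,4.69,Fe(H2O)2,-1.89
A,10,mPW2PLYP,hh-GGA,55.00,3.08,4.69,Fe(H2O)4,-4.69
A,10,mPW2PLYP,hh-GGA,55.00,3.08,4.69,Fe(H2O)6,-2.19
B,1,BMK,hm-GGA,42.00,2.02,3.71,Fe(H2O)3(CH3O-),3.71
B,1,BMK,hm-GGA,42.00,2.02,3.71,Fe(H2O)3(CH3S-),-1.24
B,1,BMK,hm-GGA,42.00,2.02,3.71,Fe(H2O)3(NH2CH3),1.84
B,1,BMK,hm-GGA,42.00,2.02,3.71,Fe(H2O)3(HCOO-),-1.30
B,2,B3LYP,h-GGA,20.00,2.10,6.22,Fe(H2O)3(CH3O-),0.02
B,2,B3LYP,h-GGA,20.00,2.10,6.22,Fe(H2O)3(CH3S-),-0.63
B,2,B3LYP,h-GGA,20.00,2.10,6.22,Fe(H2O)3(NH2CH3),-1.55
B,2,B3LYP,h-GGA,20.00,2.10,6.22,Fe(H2O)3(HCOO-),-6.22
B,3,wB97X-D,h-GGA,22.20/100.00,2.33,4.21,Fe(H2O)3(CH3O-),-4.21
B,3,wB97X-D,h-GGA,22.20/100.00,2.33,4.21,Fe(H2O)3(CH3S-),-0.82
B,3,wB97X-D,h-GGA,22.20/100.00,2.33,4.21,Fe(H2O)3(NH2CH3),0.38
B,3,wB97X-D,h-GGA,22.20/100.00,2.33,4.21,Fe(H2O)3(HCOO-),-3.90
B,4,BB1K,hm-GGA,42.00,2.44,4.33,Fe(H2O)3(CH3O-),1.59
B,4,BB1K,hm-GGA,42.00,2.44,4.33,Fe(H2O)3(CH3S-),-4.33
B,4,BB1K,hm-GGA,42.00,2.44,4.33,Fe(H2O)3(NH2CH3),0.93
B,4,BB1K,hm-GGA,42.00,2.44,4.33,Fe(H2O)3(HCOO-),-2.92
B,5,mPWB1K,hm-GGA,44.00,2.53,3.97,Fe(H2O)3(CH3O-),2.61
B,5,mPWB1K,hm-GGA,44.00,2.53,3.97,Fe(H2O)3(CH3S-),-3.97
B,5,mPWB1K,hm-GGA,44.00,2.53,3.97,Fe(H2O)3(NH2CH3),1.61
B,5,mPWB1K,hm-GGA,44.00,2.53,3.97,Fe(H2O)3(HCOO-),-1.93
B,6,mPW1N,h-GGA,40.60,2.65,4.04,Fe(H2O)3(CH3O-),3.68
B,6,mPW1N,h-GGA,40.60,2.65,4.04,Fe(H2O)3(CH3S-),-4.04
B,6,mPW1N,h-GGA,40.60,2.65,4.04,Fe(H2O)3(NH2CH3),2.59
B,6,mPW1N,h-GGA,40.60,2.65,4.04,Fe(H2O)3(HCOO-),-0.27
B,7,mPW1B95,hm-GGA,31.00,2.72,6.02,Fe(H2O)3(CH3O-),-0.69
B,7,mPW1B95,hm-GGA,31.00,2.72,6.02,Fe(H2O)3(CH3S-),-2.45
B,7,mPW1B95,hm-GGA,31.00,2.72,6.02,Fe(H2O)3(NH2CH3),-1.71
B,7,mPW1B95,hm-GGA,31.00,2.72,6.02,Fe(H2O)3(HCOO-),-6.02
B,8,mPW1K,hm-GGA,44.00,2.96,4.30,Fe(H2O)3(CH3O-),4.22
B,8,mPW1K,hm-GGA,44.00,2.96,4.30,Fe(H2O)3(CH3S-),-4.30
B,8,mPW1K,hm-GGA,44.00,2.96,4.30,Fe(H2O)3(NH2CH3),3.01
B,8,mPW1K,hm-GGA,44.00,2.96,4.30,Fe(H2O)3(HCOO-),0.30
B,9,MN12-L,m-NGA,-,2.98,4.50,Fe(H2O)3(CH3O-),4.03
B,9,MN12-L,m-NGA,-,2.98,4.50,Fe(H2O)3(CH3S-),4.50
B,9,MN12-L,m-NGA,-,2.98,4.50,Fe(H2O)3(NH2CH3),0.56
B,9,MN12-L,m-NGA,-,2.98,4.50,Fe(H2O)3(HCOO-),-2.84
B,10,M06-2X,hm-GGA,54.00,3.07,6.93,Fe(H2O)3(CH3O-),6.93
B,10,M06-2X,hm-GGA,54.00,3.07,6.93,Fe(H2O)3(CH3S-),-2.52
B,10,M06-2X,hm-GGA,54.00,3.07,6.93,Fe(H2O)3(NH2CH3),2.21
B,10,M06-2X,hm-GGA,54.00,3.07,6.93,Fe(H2O)3(HCOO-),0.63
C,1,mPW1B95,hm-GGA,31.00,1.65,3.26,Fe(H2O)5(CH3O-),-1.73
C,1,mPW1B95,hm-GGA,31.00,1.65,3.26,Fe(H2O)5(CH3S-),-3.26
C,1,mPW1B95,hm-GGA,31.00,1.65,3.26,Fe(H2O)5(NH2CH3),0.86
C,1,mPW1B95,hm-GGA,31.00,1.65,3.26,Fe(H2O)5(HCOO-),0.74
C,2,PBE1PBE,h-GGA,25.00,1.71,3.48,Fe(H2O)5(CH3O-),-2.51
C,2,PBE1PBE,h-GGA,25.00,1.71,3.48,Fe(H2O)5(CH3S-),-3.48
C,2,PBE1PBE,h-GGA,25.00,1.71,3.48,Fe(H2O)5(NH2CH3),-0.61
C,2,PBE1PBE,h-GGA,25.00,1.71,3.48,Fe(H2O)5(HCOO-),-0.25
C,3,B3PW91,h-GGA,20.00,1.73,2.60,Fe(H2O)5(CH3O-),-2.06
C,3,B3PW91,h-GGA,20.00,1.73,2.60,Fe(H2O)5(CH3S-),-2.60
C,3,B3PW91,h-GGA,20.00,1.73,2.60,Fe(H2O)5(NH2CH3),1.23
C,3,B3PW91,h-GGA,20.00,1.73,2.60,Fe(H2O)5(HCOO-),1.02
C,4,wB97X-D,h-GGA,22.20/100.00,1.99,3.43,Fe(H2O)5(CH3O-),0.38
C,4,wB97X-D,h-GGA,22.20/100.00,1.99,3.43,Fe(H2O)5(CH3S-),0.77
C,4,wB97X-D,h-GGA,22.20/100.00,1.99,3.43,Fe(H2O)5(NH2CH3),3.43
C,4,wB97X-D,h-GGA,22.20/100.00,1.99,3.43,Fe(H2O)5(HCOO-),3.39
C,5,BB1K,hm-GGA,42.00,2.03,4.47,Fe(H2O)5(CH3O-),0.23
C,5,BB1K,hm-GGA,42.00,2.03,4.47,Fe(H2O)5(CH3S-),-4.47
C,5,BB1K,hm-GGA,42.00,2.03,4.47,Fe(H2O)5(NH2CH3),1.68
C,5,BB1K,hm-GGA,42.00,2.03,4.47,Fe(H2O)5(HCOO-),1.76
C,6,mPWB1K,hm-GGA,44.00,2.29,3.98,Fe(H2O)5(CH3O-),1.05
C,6,mPWB1K,hm-GGA,44.00,2.29,3.98,Fe(H2O)5(CH3S-),-3.98
C,6,mPWB1K,hm-GGA,44.00,2.29,3.98,Fe(H2O)5(NH2CH3),1.92
C,6,mPWB1K,hm-GGA,44.00,2.29,3.98,Fe(H2O)5(HCOO-),2.20
C,7,B3LYP,h-GGA,20.00,2.38,3.22,Fe(H2O)5(CH3O-),-0.41
C,7,B3LYP,h-GGA,20.00,2.38,3.22,Fe(H2O)5(CH3S-),-3.08
C,7,B3LYP,h-GGA,20.00,2.38,3.22,Fe(H2O)5(NH2CH3),3.22
C,7,B3LYP,h-GGA,20.00,2.38,3.22,Fe(H2O)5(HCOO-),2.82
C,8,B1LYP,h-GGA,25.00,2.81,7.23,Fe(H2O)5(CH3O-),-2.53
C,8,B1LYP,h-GGA,25.00,2.81,7.23,Fe(H2O)5(CH3S-),-7.23
C,8,B1LYP,h-GGA,25.00,2.81,7.23,Fe(H2O)5(NH2CH3),0.90
C,8,B1LYP,h-GGA,25.00,2.81,7.23,Fe(H2O)5(HCOO-),0.57
C,9,B97-1,h-GGA,21.00,2.82,4.10,Fe(H2O)5(CH3O-),-3.38
C,9,B97-1,h-GGA,21.00,2.82,4.10,Fe(H2O)5(CH3S-),-4.10
C,9,B97-1,h-GGA,21.00,2.82,4.10,Fe(H2O)5(NH2CH3),-0.35
C,9,B97-1,h-GGA,21.00,2.82,4.10,Fe(H2O)5(HCOO-),-3.46
C,10,M06-2X,hm-GGA,54.00,2.91,4.77,Fe(H2O)5(CH3O-),4.77
C,10,M06-2X,hm-GGA,54.00,2.91,4.77,Fe(H2O)5(CH3S-),-2.43
C,10,M06-2X,hm-GGA,54.00,2.91,4.77,Fe(H2O)5(NH2CH3),1.39
C,10,M06-2X,hm-GGA,54.00,2.91,4.77,Fe(H2O)5(HCOO-),3.05
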