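table,column,stat,value
table3,cbs_minus_dz,MSE,-6.09
table3,cbs_minus_dz,MUE,6.09
table3,cbs_minus_tz,MSE,-3.54
table3,cbs_minus_tz,MUE,3.54
table3,cbs_minus_qz,MSE,-1.40
table3,cbs_minus_qz,MUE,1.40
table4,scheme1_minus_scheme2,MSE,-0.52
table4,scheme1_minus_scheme2,MUE,0.52
table4,scheme2_minus_qz,MSE,-0.88
table4,scheme2_minus_qz,MUE,0.88
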