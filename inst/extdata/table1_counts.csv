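variable,level,code,lvi_neg,lvi_pos
menopausal_status,premenopausal,0,83,28
menopausal_status,postmenopausal,1,97,31
location,left,0,100,26
location,right,1,80,33
tic_curve,type1,1,8,3
tic_curve,type2,2,75,19
tic_curve,type3,3,97,37
fgt_density,dense,1,42,8
fgt_density,heterogeneously_dense,2,59,27
fgt_density,scattered,3,54,19
fgt_density,predominantly_fatty,4,25,5
bpe,none_minimal,1,49,15
bpe,mild,2,79,25
bpe,moderate,3,34,13
bpe,marked,4,18,6
intratumoral_high_signal,absence,0,123,42
intratumoral_high_signal,presence,1,57,17
peritumoral_edema,absence,0,143,20
peritumoral_edema,presence,1,37,39
subcutaneous_edema,absence,0,151,46
subcutaneous_edema,presence,1,29,13
intratumoral_necrosis,absence,0,148,46
intratumoral_necrosis,presence,1,32,13
internal_enhancement,homogeneous,1,149,43
internal_enhancement,heterogeneous,2,30,15
internal_enhancement,rim_enhancement,3,1,1
adjacent_vessel_sign,absence,0,79,16
adjacent_vessel_sign,presence,1,101,43
increased_ipsilateral_vascularity,absence,0,96,29
increased_ipsilateral_vascularity,presence,1,84,30
mraln_status,absence,0,144,45
mraln_status,presence,1,36,14
dwi_rim_sign,absence,0,147,30
dwi_rim_sign,presence,1,33,29
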