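group,stimulus,mean_count
surface,water,6.00
surface,NaCl,2.25
surface,LCA,10.69
surface,adenosine,9.56
surface,cadaverine,4.81
surface,alanine,24.19
surface,NH4Cl,3.94
cave,water,15.31
cave,NaCl,3.13
cave,LCA,18.75
cave,adenosine,7.19
cave,cadaverine,5.81
cave,alanine,20.88
cave,NH4Cl,2.50
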