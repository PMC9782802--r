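individual_id,treatment,dose_uM,day,stage,eggs
ind001,control,NA,0,L3,0
ind001,control,NA,1,L3,0
ind001,control,NA,2,L3,0
ind001,control,NA,3,L3,0
ind001,control,NA,4,L3,0
ind001,control,NA,5,L4,0
ind001,control,NA,6,L4,0
ind001,control,NA,7,L4,0
ind001,control,NA,8,L4,0
ind001,control,NA,9,L4,0
ind001,control,NA,10,L5,0
ind001,control,NA,11,L5,0
ind001,control,NA,12,L5,0
ind001,control,NA,13,L5,0
ind001,control,NA,14,L5,0
ind001,control,NA,15,pupa,0
ind001,control,NA,16,pupa,0
ind001,control,NA,17,pupa,0
ind001,control,NA,18,pupa,0
ind001,control,NA,19,pupa,0
ind001,control,NA,20,pupa,0
ind001,control,NA,21,pupa,0
ind001,control,NA,22,pupa,0
ind001,control,NA,23,pupa,0
ind001,control,NA,24,pupa,0
ind001,control,NA,25,adult_female,0
ind001,control,NA,26,adult_female,0
ind001,control,NA,27,adult_female,50
ind001,control,NA,28,adult_female,80
ind001,control,NA,29,adult_female,40
ind001,control,NA,30,dead,0
ind002,control,NA,0,L3,0
ind002,control,NA,1,L3,0
ind002,control,NA,2,L3,0
ind002,control,NA,3,L3,0
ind002,control,NA,4,L4,0
ind002,control,NA,5,L4,0
ind002,control,NA,6,L4,0
ind002,control,NA,7,L4,0
ind002,control,NA,8,L4,0
ind002,control,NA,9,L5,0
ind002,control,NA,10,L5,0
ind002,control,NA,11,L5,0
ind002,control,NA,12,L5,0
ind002,control,NA,13,L5,0
ind002,control,NA,14,pupa,0
ind002,control,NA,15,pupa,0
ind002,control,NA,16,pupa,0
ind002,control,NA,17,pupa,0
ind002,control,NA,18,pupa,0
ind002,control,NA,19,pupa,0
ind002,control,NA,20,pupa,0
ind002,control,NA,21,pupa,0
ind002,control,NA,22,pupa,0
ind002,control,NA,23,pupa,0
ind002,control,NA,24,adult_male,0
ind002,control,NA,25,adult_male,0
ind002,control,NA,26,adult_male,0
ind002,control,NA,27,adult_male,0
ind002,control,NA,28,adult_male,0
ind002,control,NA,29,dead,0
ind003,control,NA,0,L3,0
ind003,control,NA,1,L3,0
ind003,control,NA,2,L3,0
ind003,control,NA,3,L3,0
ind003,control,NA,4,L3,0
ind003,control,NA,5,L4,0
ind003,control,NA,6,L4,0
ind003,control,NA,7,L4,0
ind003,control,NA,8,dead,0
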