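code,name,group,atlas,is_lesion,alarm_rule,dd_associated,severity_sensitive
TS,Thin sole,TS,TRUE,TRUE,none,FALSE,FALSE
IP,Interdigital phlegmon,IP,TRUE,TRUE,always,FALSE,FALSE
SW,Swelling of coronet and/or bulb,SW,TRUE,TRUE,always,FALSE,FALSE
HF,Horn fissure (vertical),HF,TRUE,TRUE,none,FALSE,FALSE
HFH,Horn fissure (horizontal),HF,TRUE,TRUE,none,FALSE,FALSE
GR,Horizontal groove,other,TRUE,TRUE,none,FALSE,FALSE
AX,Axial horn fissure,other,TRUE,TRUE,none,FALSE,FALSE
IH,Interdigital hyperplasia,IH,TRUE,TRUE,none,FALSE,FALSE
DS,Double sole,DS,TRUE,TRUE,none,FALSE,TRUE
CC,Corkscrew claw,CC,TRUE,TRUE,none,FALSE,FALSE
SC,Scissor claw,other,TRUE,TRUE,none,FALSE,FALSE
HHE,Heel horn erosion,HHE,TRUE,TRUE,none,FALSE,TRUE
SH-D,Sole haemorrhage (diffuse),SH,TRUE,TRUE,none,FALSE,TRUE
SH-C,Sole haemorrhage (circumscribed),SH,TRUE,TRUE,none,FALSE,TRUE
WLD,White line disease,WLD,TRUE,TRUE,sev2plus,FALSE,TRUE
SU,Sole ulcer,UL,TRUE,TRUE,always,FALSE,FALSE
TU,Toe ulcer,UL,TRUE,TRUE,always,FALSE,FALSE
BU,Bulb ulcer,UL,TRUE,TRUE,always,FALSE,FALSE
TN,Toe necrosis,UL,TRUE,TRUE,always,FALSE,FALSE
CD,Concave dorsal wall,CD,TRUE,TRUE,none,FALSE,FALSE
ID,Interdigital dermatitis,other,TRUE,TRUE,none,FALSE,FALSE
ACL,Asymmetric claw,other,TRUE,TRUE,none,FALSE,FALSE
CE,Corium exposure at the sole,other,TRUE,TRUE,none,FALSE,FALSE
HF-P,Penetrating infected horn fissure,HF,FALSE,TRUE,always,FALSE,FALSE
SU-DD,Non-healing sole ulcer (DD-associated),UL,FALSE,TRUE,always,TRUE,FALSE
BU-DD,Non-healing bulb ulcer (DD-associated),UL,FALSE,TRUE,always,TRUE,FALSE
WL-DD,Non-healing white line lesion (DD-associated),WLA,FALSE,TRUE,always,TRUE,FALSE
M0,Digital dermatitis stage M0 (healthy skin),,FALSE,FALSE,none,FALSE,FALSE
M1,Digital dermatitis stage M1 (early),DD,FALSE,TRUE,none,FALSE,FALSE
M2,Digital dermatitis stage M2 (acute ulcerative),DD,FALSE,TRUE,always,FALSE,FALSE
M3,Digital dermatitis stage M3 (healing),DD,FALSE,TRUE,none,FALSE,FALSE
M4,Digital dermatitis stage M4 (chronic),DD,FALSE,TRUE,none,FALSE,FALSE
M4.1,Digital dermatitis stage M4.1 (chronic reactivating),DD,FALSE,TRUE,none,FALSE,FALSE
NL,No lesion observed,,FALSE,FALSE,none,FALSE,FALSE
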