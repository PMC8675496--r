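group_id,label,include_prefixes
CKD,Chronic kidney disease,N18
CVD,Ischaemic heart disease and heart failure,I20;I21;I22;I23;I24;I25;I50
PAD,Peripheral arterial disease,I70;I73
VTE,Venous thromboembolism history,I26;I80;I82
PARKINSONISM,Parkinsonism and movement disorders,G20;G21;G25
HEPATIC,Hepatic impairment,K70;K71;K72;K74
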