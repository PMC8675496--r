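# Top published interaction pairs 2016-2018 (directional original -> conflicting ingredient); accepted counts were not printed.
row,col,generated,accepted,pct_printed
Ibuprofen -> Acetylsalicylic acid,sum,97847,,19
Amlodipine -> Simvastatin,sum,85358,,24
Naproxen -> Acetylsalicylic acid,sum,64913,,16
Simvastatin -> Amlodipine,sum,59453,,26
Dexketoprofen -> Acetylsalicylic acid,sum,32455,,16
Acenocoumarol -> Simvastatin,sum,31349,,29
Simvastatin -> Acenocoumarol,sum,31349,,26
Tramadol and paracetamol -> Citalopram,sum,27479,,24
Tramadol and paracetamol -> Sertraline,sum,26872,,24
Diclofenac -> Acetylsalicylic acid,sum,25292,,24
Enoxaparin -> Acetylsalicylic acid,sum,23715,,16
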