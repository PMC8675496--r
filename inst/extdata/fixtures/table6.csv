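# Top published geriatric (age >= 75) alert-generating drugs 2016-2018; accepted counts were not printed.
row,col,generated,accepted,pct_printed
Alprazolam,sum,65910,,24
Dexketoprofen,sum,45293,,24
Doxazosin,sum,33867,,30
Clonazepam,sum,23887,,35
Zolpidem,sum,23314,,25
Pentoxifylline,sum,20395,,31
Metoclopramide,sum,19098,,28
Hydroxyzine,sum,18328,,29
Etoricoxib,sum,15729,,18
Potassium clorazepate,sum,15468,,29
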