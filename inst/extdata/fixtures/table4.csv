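# Regulatory (AEMPS) safety alerts generated / accepted / printed % by year; canagliflozin entered the content in 2017.
row,col,generated,accepted,pct_printed
TRIPLE WHAMMY,2016,46020,13867,30
TRIPLE WHAMMY,2017,76107,18992,25
TRIPLE WHAMMY,2018,73860,15988,22
DICLOFENAC,2016,7288,2588,36
DICLOFENAC,2017,5734,1774,31
DICLOFENAC,2018,5137,1511,29
COXIBS,2016,3131,888,28
COXIBS,2017,2535,616,24
COXIBS,2018,2986,644,22
ACECLOFENAC,2016,805,204,25
ACECLOFENAC,2017,665,127,19
ACECLOFENAC,2018,487,101,21
ESCITALOPRAM,2016,645,204,32
ESCITALOPRAM,2017,270,95,35
ESCITALOPRAM,2018,305,72,24
CITALOPRAM,2016,495,189,38
CITALOPRAM,2017,217,67,31
CITALOPRAM,2018,302,104,34
CILOSTAZOL,2016,193,70,36
CILOSTAZOL,2017,181,66,36
CILOSTAZOL,2018,289,65,22
AGOMELATINE,2016,133,54,41
AGOMELATINE,2017,175,54,31
AGOMELATINE,2018,249,72,29
IVABRADINE,2016,130,51,39
IVABRADINE,2017,153,56,37
IVABRADINE,2018,200,48,24
CANAGLIFLOZIN,2017,128,42,33
CANAGLIFLOZIN,2018,177,40,23
TRIMETAZIDINE,2016,115,62,54
TRIMETAZIDINE,2017,82,36,44
TRIMETAZIDINE,2018,111,47,42
RALOXIFENE and BAZEDOXIFENE,2016,106,64,60
RALOXIFENE and BAZEDOXIFENE,2017,23,11,48
RALOXIFENE and BAZEDOXIFENE,2018,30,20,67
STRONTIUM RANELATE,2016,53,39,74
STRONTIUM RANELATE,2017,21,11,52
STRONTIUM RANELATE,2018,22,5,23
ALISKIREN,2016,32,21,66
ALISKIREN,2017,17,11,65
ALISKIREN,2018,3,3,100
Total,2016,59146,18301,31
Total,2017,86308,21958,25
Total,2018,84158,18720,22
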