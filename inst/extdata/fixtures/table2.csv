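# Alerts generated / accepted / printed % by MRP family and year, 2016-2018, as published for the production deployment this engine models.
row,col,generated,accepted,pct_printed
Interactions,2016,439507,118485,27
Interactions,2017,550692,138947,25
Interactions,2018,701687,166452,24
Interactions,sum,1691886,423884,25
Duplicate therapies,2016,426506,141371,33
Duplicate therapies,2017,463418,136097,29
Duplicate therapies,2018,546797,148943,27
Duplicate therapies,sum,1436721,426411,30
Advised due to age (> 75 years),2016,108974,32345,30
Advised due to age (> 75 years),2017,144807,41740,29
Advised due to age (> 75 years),2018,188139,50299,27
Advised due to age (> 75 years),sum,441920,124384,28
AEMPS safety alerts,2016,59146,18301,31
AEMPS safety alerts,2017,86308,21958,25
AEMPS safety alerts,2018,84158,18720,22
AEMPS safety alerts,sum,229612,58979,26
Contraindications due to health issues,2016,35164,13771,39
Contraindications due to health issues,2017,67452,21330,32
Contraindications due to health issues,2018,105749,28390,27
Contraindications due to health issues,sum,208365,63491,30
Teratogens in pregnancy,2016,11721,4200,36
Teratogens in pregnancy,2017,10938,3830,35
Teratogens in pregnancy,2018,11404,3709,33
Teratogens in pregnancy,sum,34063,11739,34
Combinations of anticholinergic drugs,2016,1077,423,39
Combinations of anticholinergic drugs,2017,2619,863,33
Combinations of anticholinergic drugs,2018,3171,877,28
Combinations of anticholinergic drugs,sum,6867,2163,31
Suspicions of hypersensitivity,2016,76883,28952,38
Suspicions of hypersensitivity,2017,84099,29759,35
Suspicions of hypersensitivity,2018,93852,30568,33
Suspicions of hypersensitivity,sum,254834,89279,35
Adverse drug reactions,2016,15397,4884,32
Adverse drug reactions,2017,23712,6927,29
Adverse drug reactions,2018,36489,10018,27
Adverse drug reactions,sum,75598,21829,29
Totals,2016,1174375,362732,31
Totals,2017,1434045,401451,28
Totals,2018,1771446,457976,26
Totals,sum,4379866,1222159,28
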