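# Geriatric (age >= 75) pharmacological groups, alerts generated / accepted / printed % 2016-2018. The benzodiazepine row prints 27 although 47966/172574 rounds to 28; that single printed cell departs from the otherwise uniform round-half-away convention.
row,col,generated,accepted,pct_printed
"Benzodiazepines, hypnotics, and sedatives",sum,172574,47966,27
"Anti-inflammatory and anti-rheumatic (NSAIDs, COXIBS)",sum,94034,20627,22
Antihypertensives,sum,34542,10310,30
"Digestive system (otilonium, metoclopramide, glibenclamide, chlorpropamide)",sum,31496,8945,28
Chronic obstructive pulmonary disease treatments (theophylline),sum,19285,4758,25
Central action muscle relaxants (cyclobenzaprine),sum,18170,7521,41
Tricyclic antidepressants and Fluoxetine,sum,17289,5654,33
"Peripheral vasodilators (pentoxifylline, nicergoline, naftidrofuryl)",sum,16958,6621,39
Respiratory system (systemic antihistamines),sum,14219,4917,35
Hormone therapy (megestrol),sum,10776,2631,24
Urinary antispasmodics (oxybutynin),sum,7018,2495,36
Antithrombotics (cilostazol),sum,3270,1100,34
Beta-blockers (sotalol),sum,1105,392,35
Opioid and anti-migraine pain relievers,sum,868,342,39
Antiparkinsonian drugs,sum,316,105,33
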