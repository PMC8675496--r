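rule_id,group,min_age,severity,risk_text,alternatives
G-BENZO,BENZODIAZEPINES,75,ORANGE,Benzodiazepines and hypnotic sedatives increase fall and fracture risk in patients aged 75 and over,
G-NSAID,GERI_NSAID,75,ORANGE,NSAIDs and COXIBs carry renal gastrointestinal and cardiovascular risk in patients aged 75 and over,paracetamol
G-ANTIHYPERT,ANTIHYPERTENSIVES_GERI,75,ORANGE,Alpha-blocker antihypertensives cause orthostatic hypotension in old age,
G-DIGESTIVE,DIGESTIVE_GERI,75,ORANGE,Digestive-system drugs with unfavourable risk-benefit in old age,
G-THEOPHYLLINE,THEOPHYLLINE,75,ORANGE,Theophylline has a narrow therapeutic margin in old age,
G-MUSCLE-RELAX,MUSCLE_RELAXANTS,75,ORANGE,Central muscle relaxants cause sedation and anticholinergic effects in old age,
G-TCA-FLUOX,TCA_FLUOXETINE,75,ORANGE,Tricyclic antidepressants and fluoxetine are poorly tolerated in old age,sertraline
G-VASODIL,PERIPHERAL_VASODILATORS,75,ORANGE,Peripheral vasodilators lack proven benefit and cause hypotension in old age,
G-ANTIHIST,ANTIHISTAMINES_SYSTEMIC,75,ORANGE,Systemic antihistamines are strongly anticholinergic in old age,
G-MEGESTROL,MEGESTROL,75,ORANGE,Megestrol increases thrombotic risk with minimal benefit in old age,
G-OXYBUTYNIN,OXYBUTYNIN,75,ORANGE,Oxybutynin is strongly anticholinergic in old age,
G-CILOSTAZOL,CILOSTAZOL,75,ORANGE,Cilostazol is poorly tolerated in old age,
G-SOTALOL,SOTALOL,75,ORANGE,Sotalol carries proarrhythmic risk in old age,
G-OPIOID-MIGRAINE,OPIOID_MIGRAINE_GERI,75,ORANGE,Selected opioid and anti-migraine analgesics are inappropriate in old age,
G-ANTIPARK,ANTIPARKINSONIANS,75,ORANGE,Selected antiparkinsonian drugs are inappropriate in old age,
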