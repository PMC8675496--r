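rule_id,group,variable_label,comparator,threshold,unit,severity,risk_text
CV-NSAID-EGFR,NSAIDS,eGFR,<,30,mL/min/1.73m2,ORANGE,NSAIDs are contraindicated with an estimated glomerular filtration rate below 30
CV-RAS-K,RAS_INHIBITORS,potassium,>,5.5,mmol/L,ORANGE,Renin-angiotensin system inhibitors worsen hyperkalaemia
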