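rule_id,group,subtype,severity,risk_text
D-NSAID,NSAIDS,clinically_relevant,ORANGE,Two concomitant NSAIDs add toxicity without added analgesic benefit
D-PARACETAMOL,ANALGESICS_PARACETAMOL,clinically_relevant,ORANGE,Concomitant paracetamol-containing products risk exceeding the maximum daily dose
D-RAS,RAS_INHIBITORS,dose_adjustment,ORANGE,Two renin-angiotensin system inhibitors; verify whether a dose adjustment rather than a new drug is intended
D-GASTRIC,GASTRIC_PROTECTORS,clinically_relevant,ORANGE,Duplicate gastric protection without added benefit
D-SSRI,SSRI,dose_adjustment,ORANGE,Two SSRI antidepressants; verify whether a dose adjustment or a switch is intended
D-ANTIBIOTIC,ANTIBIOTICS_BETALACTAM,dose_adjustment,ORANGE,Overlapping beta-lactam courses; verify whether a replacement rather than an addition is intended
D-ANTICOAG,ANTICOAGULANTS_ORAL,clinically_relevant,ORANGE,Duplicate oral anticoagulation carries a high risk of serious bleeding
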