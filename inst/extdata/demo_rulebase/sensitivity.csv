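rule_id,kind,group,severity,risk_text
S-HS-NSAID,suspected_hypersensitivity,XR_NSAIDS,ORANGE,Recorded suspected hypersensitivity to NSAIDs; cross-reactivity within the class is common
S-HS-BETALACTAM,suspected_hypersensitivity,ANTIBIOTICS_BETALACTAM,ORANGE,Recorded suspected hypersensitivity to beta-lactam antibiotics alone or in combination
S-ADR-NSAID,adverse_drug_reaction,XR_NSAIDS,ORANGE,Recorded adverse drug reaction to NSAIDs
S-ADR-SSRI,adverse_drug_reaction,SSRI,ORANGE,Recorded adverse drug reaction to SSRI antidepressants
S-ADR-BETALACTAM,adverse_drug_reaction,ANTIBIOTICS_BETALACTAM,ORANGE,Recorded adverse drug reaction to beta-lactam antibiotics
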