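rule_id,group,severity,risk_text
T-NSAID-PREG,TERATOGENS_DEMO,RED,NSAIDs and acetylsalicylic acid risk premature ductus arteriosus closure and other fetal harm in pregnancy
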