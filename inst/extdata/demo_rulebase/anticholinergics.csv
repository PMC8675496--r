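rule_id,group,min_concomitant,severity,risk_text
AC-DEMO,ANTICHOL_DEMO,1,ORANGE,Combining anticholinergic drugs raises the cumulative anticholinergic burden
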