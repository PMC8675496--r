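rule_id,group,problem_group,severity,risk_text
PC-NSAID-CKD,NSAIDS,CKD,ORANGE,NSAIDs worsen renal function in chronic kidney disease
PC-SULFONYLUREA-CKD,SULFONYLUREAS_LONG,CKD,ORANGE,Long-acting sulfonylureas accumulate and cause hypoglycaemia in chronic kidney disease
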