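rule_id,label,trigger_group,required_comed_groups,min_age,max_age,problem_groups,dose_comparator,dose_threshold,dose_unit,severity,risk_text,alternatives
A-TRIPLE-WHAMMY,TRIPLE WHAMMY,NSAIDS,RAS_INHIBITORS;DIURETICS,,,,,,,RED,Concomitant NSAID with a renin-angiotensin system inhibitor and a diuretic markedly increases the risk of acute kidney injury,paracetamol
A-COXIBS,COXIBS,COXIBS,,,,CVD,,,,RED,COX-2 selective inhibitors are contraindicated in established ischaemic heart disease or heart failure,naproxen
A-DICLOFENAC,DICLOFENAC,DICLOFENAC,,,,CVD,,,,RED,Systemic diclofenac is contraindicated in established cardiovascular disease,naproxen
A-ACECLOFENAC,ACECLOFENAC,ACECLOFENAC,,,,CVD,,,,RED,Aceclofenac is contraindicated in established cardiovascular disease,naproxen
A-CILOSTAZOL,CILOSTAZOL,CILOSTAZOL,,,,CVD,,,,RED,Cilostazol is contraindicated in unstable ischaemic heart disease and heart failure,
A-IVABRADINE,IVABRADINE,IVABRADINE,,,,CVD,,,,RED,Ivabradine requires review in unstable cardiovascular disease,
A-AGOMELATINE,AGOMELATINE,AGOMELATINE,,,,HEPATIC,,,,RED,Agomelatine is contraindicated in hepatic impairment,sertraline
A-ESCITALOPRAM,ESCITALOPRAM,ESCITALOPRAM,,,,,>,20,mg,RED,Escitalopram above the maximum daily dose carries a dose-dependent QT prolongation risk,sertraline
A-CITALOPRAM,CITALOPRAM,CITALOPRAM,,,,,>,40,mg,RED,Citalopram above the maximum daily dose carries a dose-dependent QT prolongation risk,sertraline
A-TRIMETAZIDINE,TRIMETAZIDINE,TRIMETAZIDINE,,,,PARKINSONISM,,,,RED,Trimetazidine is contraindicated in parkinsonism and movement disorders,
A-RALOX-BAZEDOX,RALOXIFENE and BAZEDOXIFENE,RALOX_BAZEDOX,,,,VTE,,,,RED,Raloxifene and bazedoxifene are contraindicated with a history of venous thromboembolism,
A-STRONTIUM,STRONTIUM RANELATE,STRONTIUM,,,,CVD,,,,RED,Strontium ranelate is contraindicated in established cardiovascular disease,
A-ALISKIREN,ALISKIREN,ALISKIREN,ACEI_ARB,,,,,,,RED,Aliskiren combined with an ACE inhibitor or angiotensin receptor blocker is contraindicated,
A-CANAGLIFLOZIN,CANAGLIFLOZIN,CANAGLIFLOZIN,,,,PAD,,,,RED,Canagliflozin carries an increased amputation risk in peripheral arterial disease,
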