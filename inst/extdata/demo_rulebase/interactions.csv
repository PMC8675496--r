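rule_id,group_a,group_b,severity,risk_text,alternatives
I-NSAID-ASA,NSAIDS,ASA,ORANGE,NSAIDs blunt the antiplatelet effect of acetylsalicylic acid and increase gastrointestinal bleeding risk,paracetamol
I-CCB-STATIN,AMLODIPINE,SIMVASTATIN,ORANGE,Amlodipine raises simvastatin exposure and the risk of myopathy; limit simvastatin to 20 mg daily,pravastatin
I-COUMARIN-STATIN,ACENOCOUMAROL,SIMVASTATIN,ORANGE,Simvastatin potentiates coumarin anticoagulants; monitor INR on initiation,pravastatin
I-TRAMADOL-SSRI,TRAMADOL,SSRI,ORANGE,Combination of tramadol with SSRIs increases the risk of serotonin syndrome and lowers the seizure threshold,paracetamol
I-HEPARIN-ASA,ENOXAPARIN,ASA,ORANGE,Concomitant low-molecular-weight heparin and acetylsalicylic acid increases bleeding risk,
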