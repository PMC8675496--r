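# Counts quoted only in the running text of the published audit summary.
name,value
new_prescriptions_millions_2016,22.5
new_prescriptions_millions_2017,22.3
new_prescriptions_millions_2018,22.4
nsaid_hypersensitivity_alerts,113936
ibuprofen_hypersensitivity_alerts,61026
betalactam_hypersensitivity_alerts,39622
betalactam_hypersensitivity_accepted,25153
teratogen_ibuprofen_alerts,10864
teratogen_asa_alerts,4336
nsaid_asa_interaction_generated,220507
nsaid_asa_interaction_accepted,40227
top5_duplication_pairs_generated,317390
top5_duplication_pairs_accepted,144450
four_main_duplication_groups_generated,600930
amoxicillin_duplication_generated,76409
anticoagulant_duplication_generated,14903
anticoagulant_duplication_accepted,6314
analgesic_duplication_accepted,88435
gastric_protector_duplication_accepted,33245
ssri_duplication_accepted,10753
ras_duplication_accepted,20940
benzodiazepine_geriatric_2016,30662
benzodiazepine_geriatric_2018,68974
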