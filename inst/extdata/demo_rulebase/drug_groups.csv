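group_id,label,include_prefixes,exclude_prefixes,member_ingredients
NSAIDS,NSAIDs (systemic),M01A,M01AX,
COXIBS,COX-2 selective inhibitors,M01AH,,
ASA,Acetylsalicylic acid (antiplatelet),B01AC06,,acetylsalicylic_acid
RAS_INHIBITORS,Renin-angiotensin system inhibitors,C09,,
ACEI_ARB,ACE inhibitors and angiotensin receptor blockers,C09A;C09B;C09C;C09D,,
DIURETICS,Diuretics,C03,,
SIMVASTATIN,Simvastatin,C10AA01,,simvastatin
AMLODIPINE,Amlodipine,C08CA01,,amlodipine
ACENOCOUMAROL,Acenocoumarol,B01AA07,,acenocoumarol
ENOXAPARIN,Enoxaparin,B01AB05,,enoxaparin
TRAMADOL,Tramadol-containing analgesics,N02AX02,,tramadol
SSRI,Selective serotonin reuptake inhibitors,N06AB,,
GASTRIC_PROTECTORS,Proton pump inhibitors and gastric protectors,A02B,,
ANALGESICS_PARACETAMOL,Paracetamol-type analgesics,N02BE,,paracetamol
ANTIBIOTICS_BETALACTAM,Beta-lactam antibiotics alone or in combination,J01C,,
ANTICOAGULANTS_ORAL,Oral anticoagulants,B01AA,,
BENZODIAZEPINES,Benzodiazepines and hypnotic sedatives,N05BA;N05CD;N05CF,,clonazepam
GERI_NSAID,NSAIDs and COXIBs (geriatric caution),M01A,,
ANTIHYPERTENSIVES_GERI,Antihypertensives inappropriate in old age,C02CA,,doxazosin
DIGESTIVE_GERI,Digestive-system drugs inappropriate in old age,,,metoclopramide;glibenclamide;chlorpropamide;otilonium
THEOPHYLLINE,Theophylline,R03DA,,theophylline
MUSCLE_RELAXANTS,Central action muscle relaxants,M03B,,cyclobenzaprine
TCA_FLUOXETINE,Tricyclic antidepressants and fluoxetine,N06AA,,fluoxetine
PERIPHERAL_VASODILATORS,Peripheral vasodilators,C04,,pentoxifylline;nicergoline;naftidrofuryl
ANTIHISTAMINES_SYSTEMIC,Systemic antihistamines,N05BB;R06A,,hydroxyzine
MEGESTROL,Megestrol,L02AB,,megestrol
OXYBUTYNIN,Oxybutynin,G04BD04,,oxybutynin
CILOSTAZOL,Cilostazol,B01AC23,,cilostazol
SOTALOL,Sotalol,C07AA07,,sotalol
OPIOID_MIGRAINE_GERI,Opioid and anti-migraine analgesics (geriatric caution),N02AB;N02C,,
ANTIPARKINSONIANS,Antiparkinsonian drugs,N04,,
ANTICHOL_DEMO,Anticholinergic burden drugs,,,hydroxyzine;oxybutynin;cyclobenzaprine
TERATOGENS_DEMO,Teratogens in pregnancy,,,ibuprofen;acetylsalicylic_acid
XR_NSAIDS,NSAID cross-reactivity group,M01A;N02BA,,acetylsalicylic_acid
DICLOFENAC,Diclofenac (systemic),M01AB05,,diclofenac
ACECLOFENAC,Aceclofenac,M01AB16,,aceclofenac
CITALOPRAM,Citalopram,N06AB04,,citalopram
ESCITALOPRAM,Escitalopram,N06AB10,,escitalopram
IVABRADINE,Ivabradine,C01EB17,,ivabradine
AGOMELATINE,Agomelatine,N06AX22,,agomelatine
TRIMETAZIDINE,Trimetazidine,C01EB15,,trimetazidine
RALOX_BAZEDOX,Raloxifene and bazedoxifene,G03XC,,raloxifene;bazedoxifene
STRONTIUM,Strontium ranelate,M05BX03,,strontium_ranelate
ALISKIREN,Aliskiren,C09XA02,,aliskiren
CANAGLIFLOZIN,Canagliflozin,A10BK02,,canagliflozin
SULFONYLUREAS_LONG,Long-acting sulfonylureas,A10BB01;A10BB02,,glibenclamide;chlorpropamide
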