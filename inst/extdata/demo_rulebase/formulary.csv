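product_id,label,atc,ingredients
ibuprofen,Ibuprofen,M01AE01,ibuprofen
naproxen,Naproxen,M01AE02,naproxen
dexketoprofen,Dexketoprofen,M01AE17,dexketoprofen
diclofenac,Diclofenac,M01AB05,diclofenac
aceclofenac,Aceclofenac,M01AB16,aceclofenac
acetylsalicylic_acid,Acetylsalicylic acid,B01AC06,acetylsalicylic_acid
paracetamol,Paracetamol,N02BE01,paracetamol
tramadol,Tramadol,N02AX02,tramadol
tramadol_paracetamol,Tramadol and paracetamol,N02AJ13,tramadol;paracetamol
omeprazole,Omeprazole,A02BC01,omeprazole
metamizole,Metamizole,N02BB02,metamizole
simvastatin,Simvastatin,C10AA01,simvastatin
amlodipine,Amlodipine,C08CA01,amlodipine
acenocoumarol,Acenocoumarol,B01AA07,acenocoumarol
enoxaparin,Enoxaparin,B01AB05,enoxaparin
citalopram,Citalopram,N06AB04,citalopram
escitalopram,Escitalopram,N06AB10,escitalopram
sertraline,Sertraline,N06AB06,sertraline
fluoxetine,Fluoxetine,N06AB03,fluoxetine
alprazolam,Alprazolam,N05BA12,alprazolam
clonazepam,Clonazepam,N03AE01,clonazepam
zolpidem,Zolpidem,N05CF02,zolpidem
potassium_clorazepate,Potassium clorazepate,N05BA05,potassium_clorazepate
doxazosin,Doxazosin,C02CA04,doxazosin
pentoxifylline,Pentoxifylline,C04AD03,pentoxifylline
nicergoline,Nicergoline,C04AE02,nicergoline
naftidrofuryl,Naftidrofuryl,C04AX21,naftidrofuryl
metoclopramide,Metoclopramide,A03FA01,metoclopramide
hydroxyzine,Hydroxyzine,N05BB01,hydroxyzine
etoricoxib,Etoricoxib,M01AH05,etoricoxib
cilostazol,Cilostazol,B01AC23,cilostazol
ivabradine,Ivabradine,C01EB17,ivabradine
agomelatine,Agomelatine,N06AX22,agomelatine
trimetazidine,Trimetazidine,C01EB15,trimetazidine
raloxifene,Raloxifene,G03XC01,raloxifene
bazedoxifene,Bazedoxifene,G03XC02,bazedoxifene
strontium_ranelate,Strontium ranelate,M05BX03,strontium_ranelate
aliskiren,Aliskiren,C09XA02,aliskiren
canagliflozin,Canagliflozin,A10BK02,canagliflozin
amoxicillin,Amoxicillin,J01CA04,amoxicillin
amoxicillin_clavulanate,Amoxicillin and clavulanic acid,J01CR02,amoxicillin;clavulanic_acid
theophylline,Theophylline,R03DA04,theophylline
cyclobenzaprine,Cyclobenzaprine,M03BX08,cyclobenzaprine
oxybutynin,Oxybutynin,G04BD04,oxybutynin
sotalol,Sotalol,C07AA07,sotalol
megestrol,Megestrol,L02AB01,megestrol
glibenclamide,Glibenclamide,A10BB01,glibenclamide
chlorpropamide,Chlorpropamide,A10BB02,chlorpropamide
otilonium,Otilonium,A03AB06,otilonium
enalapril,Enalapril,C09AA02,enalapril
furosemide,Furosemide,C03CA01,furosemide
hydrochlorothiazide,Hydrochlorothiazide,C03AA03,hydrochlorothiazide
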