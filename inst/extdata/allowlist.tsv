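phrase	category
Noonan	medical_name
Marfan	medical_name
Kabuki	medical_name
Rett	medical_name
Angelman	medical_name
Dravet	medical_name
West	medical_name
Iso Kikuchi	medical_name
Prader-Willi	medical_name
Cornelia de Lange	medical_name
Silver-Russell	medical_name
Wolf-Hirschhorn	medical_name
Coffin-Siris	medical_name
Pitt-Hopkins	medical_name
Rubinstein-Taybi	medical_name
Smith-Magenis	medical_name
Beckwith-Wiedemann	medical_name
Ehlers-Danlos	medical_name
Kleefstra	medical_name
Sotos	medical_name
valproate	drug
levetiracetam	drug
risperidone	drug
melatonin	drug
methylphenidate	drug
baclofen	drug
topiramate	drug
clobazam	drug
lamotrigine	drug
oxcarbazepine	drug
vigabatrin	drug
hydroxyzine	drug
MECP2	gene
SCN1A	gene
PTPN11	gene
FBN1	gene
UBE3A	gene
NIPBL	gene
KMT2D	gene
CDKL5	gene
STXBP1	gene
ARID1B	gene
SHANK3	gene
FOXG1	gene
TCF4	gene
DYRK1A	gene
ANKRD11	gene
ADNP	gene
CHD8	gene
SYNGAP1	gene
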