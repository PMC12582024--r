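format-version: 1.2
data-version: fixture/2026-01
ontology: hp-fixture

[Term]
id: HP:0000118
name: Phenotypic abnormality

[Term]
id: HP:0001250
name: Seizure
synonym: "Epileptic seizure" EXACT []
synonym: "Seizures" EXACT []
is_a: HP:0000118 ! Phenotypic abnormality

[Term]
id: HP:0000252
name: Microcephaly
synonym: "Small head" BROAD []
is_a: HP:0000118 ! Phenotypic abnormality

[Term]
id: HP:0001252
name: Muscular hypotonia
synonym: "Low muscle tone" EXACT []
is_a: HP:0000118 ! Phenotypic abnormality

[Term]
id: HP:0001249
name: Intellectual disability
synonym: "Mental retardation" RELATED []
is_a: HP:0000118 ! Phenotypic abnormality

[Term]
id: HP:0002650
name: Scoliosis
is_a: HP:0000118 ! Phenotypic abnormality

[Term]
id: HP:0000175
name: Cleft palate
is_a: HP:0000118 ! Phenotypic abnormality

[Term]
id: HP:0001629
name: Ventricular septal defect
is_a: HP:0000118 ! Phenotypic abnormality

[Term]
id: HP:0009999
name: obsolete Seizure-like episodes
is_obsolete: true
replaced_by: HP:0001250
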