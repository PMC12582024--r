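phrase	category
Montpellier	location
Nîmes	location
Paris	location
Lyon	location
Marseille	location
Toulouse	location
Nantes	location
Lille	location
Bordeaux	location
Strasbourg	location
Rennes	location
Grenoble	location
Dijon	location
Angers	location
Avignon	location
Perpignan	location
Béziers	location
Sète	location
Alès	location
Nancy	location
Occitanie	location
Hérault	location
Gard	location
Lozère	location
Aveyron	location
Carémeau	location
Lapeyronie	location
Arnaud de Villeneuve	location
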