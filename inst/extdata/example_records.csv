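record_id,taxon,species,carcass_code,body_score,systems_macro,cutaneous_score,systems_organized,systems_histo,parasitosis_score,lymphoid_depletion_score,thyroid_score
PMP-0001,seabird,Spheniscus magellanicus,2,2,digestive;respiratory,1,none,digestive,2,1,0
PMP-0002,seabird,Larus dominicanus,2,0,none,0,none,none,0,0,0
PMP-0003,sea_turtle,Chelonia mydas,2,3,digestive;respiratory;nervous,1,musculoskeletal,digestive;lympho_hematopoietic,2,2,1
PMP-0004,sea_turtle,Chelonia mydas,2,1,digestive,2,none,none,1,0,0
PMP-0005,marine_mammal,Sotalia guianensis,2,1,respiratory,0,none,respiratory;cardiovascular,1,1,1
PMP-0006,marine_mammal,Pontoporia blainvillei,3,0,none,0,none,none,0,0,0
PMP-0007,seabird,Puffinus puffinus,2,2,digestive,1,none,digestive,1,1,
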