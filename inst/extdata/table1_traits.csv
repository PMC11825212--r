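species,trophic,substrate,temperature
Auchmeromyia bequaerti,obligatory parasite,fresh,constant
Auchmeromyia luteola,obligatory parasite,fresh,constant
Cordylobia anthropophaga,obligatory parasite,fresh,constant
Pachychoeromyia praegrandis,obligatory parasite,fresh,constant
Aldrichina grahami,NA,necrotic,NA
Calliphora croceipalpis,facultative parasite,NA,both
Calliphora lata,saprophagous,necrotic,variable
Calliphora lopesi,saprophagous,necrotic,variable
Calliphora maestrica,NA,NA,NA
Calliphora nigribarbis,saprophagous,necrotic,variable
Calliphora nigribasis,saprophagous,necrotic,variable
Calliphora vicina,facultative parasite,necrotic,both
Calliphora vomitoria,facultative parasite,necrotic,both
Chrysomya albiceps,facultative parasite,both,both
Chrysomya bezziana,obligatory parasite,fresh,constant
Chrysomya chani,saprophagous,necrotic,variable
Chrysomya chloropyga,facultative parasite,necrotic,both
Chrysomya marginalis,NA,necrotic,both
Chrysomya megacephala,facultative parasite,necrotic,both
Chrysomya nigripes,saprophagous,necrotic,variable
Chrysomya pinguis,saprophagous,necrotic,variable
Chrysomya putoria,facultative parasite,necrotic,both
Chrysomya rufifacies,facultative parasite,both,both
Chrysomya thanomthini,saprophagous,necrotic,variable
Chrysomya villeneuvi,saprophagous,necrotic,variable
Cochliomyia aldrichi,NA,NA,NA
Cochliomyia hominivorax,obligatory parasite,fresh,constant
Cochliomyia macellaria,facultative parasite,necrotic,both
Cochliomyia minima,saprophagous,necrotic,variable
Compsomyiops fulvicrura,NA,NA,NA
Compsomyiops verena,saprophagous,necrotic,variable
Hemilucilia segmentaria,saprophagous,necrotic,variable
Hemilucilia semidiaphana,saprophagous,necrotic,variable
Paralucilia fulvinota,saprophagous,necrotic,variable
Paralucilia paraensis,saprophagous,necrotic,variable
Paralucilia pseudolyrcea,saprophagous,necrotic,variable
Phormia regina,facultative parasite,necrotic,both
Protocalliphora azurea,obligatory parasite,fresh,constant
Protocalliphora sialia,obligatory parasite,fresh,constant
Protophormia terraenovae,facultative parasite,both,both
Hemipyrellia fernandica,facultative parasite,necrotic,both
Hemipyrellia ligurriens,facultative parasite,necrotic,both
Hemipyrellia pulchra,saprophagous,necrotic,variable
Lucilia ampullacea,facultative parasite,necrotic,both
Lucilia caesar,facultative parasite,necrotic,both
Lucilia cluvia,saprophagous,necrotic,variable
Lucilia caeruleiviridis,saprophagous,necrotic,variable
Lucilia cuprina,facultative parasite,both,both
Lucilia eximia,facultative parasite,both,both
Lucilia fayeae,NA,NA,NA
Lucilia lucigerens,saprophagous,necrotic,variable
Lucilia mexicana,saprophagous,necrotic,variable
Lucilia papuensis,saprophagous,necrotic,variable
Lucilia porphyrina,facultative parasite,both,both
Lucilia retroversa,NA,NA,NA
Lucilia rica,NA,NA,NA
Lucilia richardsi,NA,necrotic,both
Lucilia sericata,facultative parasite,both,both
Lucilia silvarum,saprophagous,necrotic,both
Sarconesia chlorogaster,saprophagous,necrotic,variable
Sarconesia versicolor,NA,NA,NA
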