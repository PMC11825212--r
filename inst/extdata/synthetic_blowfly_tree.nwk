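(((((Cochliomyia_macellaria:0.214277227,(((Lucilia_richardsi:0.0118931147,Hemilucilia_semidiaphana:0.0118931147):0.03046441468,Hemipyrellia_pulchra:0.04235752938):0.0266496993,Compsomyiops_fulvicrura:0.06900722868):0.1452699983):0.2319409867,((Chrysomya_putoria:0.2673558941,(((Lucilia_ampullacea:0.03021202484,Lucilia_mexicana:0.03021202484):0.07411538216,Compsomyiops_verena:0.104327407):0.05369293818,((Chrysomya_marginalis:0.02462231973,Lucilia_fayeae:0.02462231973):0.1154761227,Chrysomya_albiceps:0.1400984424):0.01792190277):0.1093355489):0.07152834206,(Aldrichina_grahami:0.1896918532,Lucilia_cuprina:0.1896918532):0.1491923829):0.1073339775):0.1773712753,((((Chrysomya_thanomthini:0.02069194172,Auchmeromyia_bequaerti:0.02069194172):0.2111644949,((((Auchmeromyia_luteola:0.008413287255,Calliphora_lata:0.008413287255):0.05009857434,Lucilia_sericata:0.0585118616):0.09750526257,(Paralucilia_fulvinota:0.152762802,((Lucilia_eximia:0.09575763977,Lucilia_retroversa:0.09575763977):0.01634650503,(((Chrysomya_chani:0.005806142263,Lucilia_caeruleiviridis:0.005806142263):0.04347534165,Lucilia_porphyrina:0.04928148391):0.04064033756,Cochliomyia_aldrichi:0.08992182147):0.02218232334):0.04065865723):0.003254322132):0.06163423401,(Sarconesia_chlorogaster:0.08569520733,((Calliphora_vicina:0.01416515477,Protocalliphora_sialia:0.01416515477):0.0381258169,Calliphora_nigribasis:0.05229097166):0.03340423566):0.1319561508):0.01420507841):0.1997529786,(Cordylobia_anthropophaga:0.11052354,(Lucilia_caesar:0.040676074,Paralucilia_pseudolyrcea:0.040676074):0.06984746599):0.3210858752):0.0074601536,(Lucilia_silvarum:0.2747398724,((Calliphora_nigribarbis:0.1925098153,Lucilia_lucigerens:0.1925098153):0.00760192413,(Sarconesia_versicolor:0.1984143656,((Paralucilia_paraensis:0.009006536206,Lucilia_papuensis:0.009006536206):0.1190093681,Protocalliphora_azurea:0.1280159043):0.0703984613):0.001697373861):0.074628133):0.1643296964):0.1845199202):0.176410511,((((Chrysomya_chloropyga:0.344451672,Chrysomya_megacephala:0.344451672):0.2064390368,((Cochliomyia_minima:0.3419158223,(Calliphora_vomitoria:0.07099431456,(Hemipyrellia_fernandica:0.001265909296,Chrysomya_pinguis:0.001265909296):0.06972840527):0.2709215078):0.02402891736,(Chrysomya_bezziana:0.2045909175,((Calliphora_lopesi:0.06370795254,Lucilia_cluvia:0.06370795254):0.1392424111,((Protophormia_terraenovae:0.0756444447,Hemilucilia_segmentaria:0.0756444447):0.09925367124,(Chrysomya_villeneuvi:0.07534767388,Hemipyrellia_ligurriens:0.07534767388):0.09955044206):0.02805224767):0.001640553872):0.1613538222):0.1849459691):0.001826535453,(Calliphora_maestrica:0.310829472,((Phormia_regina:0.2033425501,(Calliphora_croceipalpis:0.1528730149,Chrysomya_rufifacies:0.1528730149):0.0504695351):0.01567433872,(Chrysomya_nigripes:0.03879176655,Cochliomyia_hominivorax:0.03879176655):0.1802251222):0.09181258322):0.2418877722):0.1278256855,(Lucilia_rica:0.5893242836,Pachychoeromyia_praegrandis:0.5893242836):0.09121864611):0.1194570703):0.2,(Sarcophaga_bullata:0.5,(Oxysarcodexia_thornax:0.1722295348,Peckia_ingens:0.1722295348):0.3277704652):0.5);
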