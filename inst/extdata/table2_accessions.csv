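family,species,coi,its2,r16s,r28s
Calliphoridae,Auchmeromyia bequaerti,,JQ246578,,JQ246626
Calliphoridae,Auchmeromyia luteola,FR719153,,,AJ551431
Calliphoridae,Aldrichina grahami,KC354374,KR105493,GQ396703,MF281687
Calliphoridae,Calliphora croceipalpis,JQ246671,JQ246573,JQ246720,JQ246616
Calliphoridae,Calliphora lata,EU880187,KR105516,,
Calliphoridae,Calliphora lopesi,KJ195705,KJ438995,,
Calliphoridae,Calliphora maestrica,MF097186,MF097581,,
Calliphoridae,Calliphora nigribarbis,KY001863,,AB465966,AB466112
Calliphoridae,Calliphora nigribasis,MG700300,KP723303,,
Calliphoridae,Calliphora vicina,JQ246672,EF560178,JQ246720,JQ246617
Calliphoridae,Calliphora vomitoria,JQ246673,EF560179,JQ246721,JQ246618
Calliphoridae,Chrysomya albiceps,JQ246659,EF560173,JQ246709,JQ246604
Calliphoridae,Chrysomya bezziana,JQ246660,EF560174,JQ246710,JQ246605
Calliphoridae,Chrysomya chani,KT894988,JQ811390,,KT894969
Calliphoridae,Chrysomya chloropyga,JQ246661,JQ246571,JQ246711,JQ246606
Calliphoridae,Chrysomya marginalis,MH765384,MH716084,,
Calliphoridae,Chrysomya megacephala,JQ246662,EF560175,,JQ246607
Calliphoridae,Chrysomya nigripes,DQ647354,JQ811379,,
Calliphoridae,Chrysomya pinguis,KY031785,MG597045,,KT894963
Calliphoridae,Chrysomya putoria,JQ246663,EF560176,JQ246712,JQ246608
Calliphoridae,Chrysomya rufifacies,JQ246664,EF560177,JQ246713,JQ24660
Calliphoridae,Chrysomya thanomthini,KY020771,,,KT894960
Calliphoridae,Chrysomya villeneuvi,KY020756,JX027540,,KT894975
Calliphoridae,Cochliomyia aldrichi,KX529529,KX529563,,KX529513
Calliphoridae,Cochliomyia hominivorax,JQ246665,EF560181,JQ246714,JQ246610
Calliphoridae,Cochliomyia macellaria,JQ246666,EF560182,JQ246715,JQ246611
Calliphoridae,Cochliomyia minima,KX529552,KX529596,,KX529507
Calliphoridae,Compsomyiops fulvicrura,FJ025607,,FJ025428,FJ025504
Calliphoridae,Compsomyiops verena,KC568265,KP723296,,
Calliphoridae,Cordylobia anthropophaga,JQ246681,JQ246579,JQ246730,JQ246627
Calliphoridae,Hemilucilia segmentaria,JQ246667,EF560192,JQ246716,JQ246612
Calliphoridae,Hemilucilia semidiaphana,JQ246668,JQ246572,JQ246717,JQ246613
Calliphoridae,Hemipyrellia fernandica,KF839571,,,AJ558191
Calliphoridae,Hemipyrellia ligurriens,JQ246676,JQ246576,JQ246725,JQ246621
Calliphoridae,Hemipyrellia pulchra,KR921680,JQ811336,KC347599,KC538814
Calliphoridae,Lucilia ampullacea,JX295666,JX295789,JX295741,JX295770
Calliphoridae,Lucilia caesar,JX295697,JX295798,JX295749,JX295779
Calliphoridae,Lucilia cluvia,JN280714,MF097626,,AJ551440
Calliphoridae,Lucilia caeruleiviridis,KR752115,MF097633,,KF839502
Calliphoridae,Lucilia cuprina,JQ246677,EF560185,JQ246726,JQ246622
Calliphoridae,Lucilia eximia,JQ246678,EF560186,JQ246727,JQ246623
Calliphoridae,Lucilia fayeae,JN280720,MF097672,,KF839510
Calliphoridae,Lucilia lucigerens,KX283408,MF097673,,
Calliphoridae,Lucilia mexicana,JN280725,MF097677,,AJ551441
Calliphoridae,Lucilia papuensis,KY031743,JQ811302,,FR719307
Calliphoridae,Lucilia porphyrina,MF694302,JQ811295,EU661341,MF694310
Calliphoridae,Lucilia retroversa,JN280712,MF097683,,
Calliphoridae,Lucilia rica,JN280711,MF097697,,
Calliphoridae,Lucilia richardsi,KJ394940,KF825991,,AJ551442
Calliphoridae,Lucilia sericata,JQ246679,EF560187,JQ246728,JQ246624
Calliphoridae,Lucilia silvarum,MG118579,KF826006,,FR719316
Calliphoridae,Pachychoeromyia praegrandis,JQ246683,JQ246581,JQ246732,JQ246629
Calliphoridae,Paralucilia fulvinota,MH688062,MH699084,MH703525,MH699111
Calliphoridae,Paralucilia paraensis,MH987770,MH699119,MH703529,
Calliphoridae,Paralucilia pseudolyrcea,MH987767,MH699087,MH703519,MH699121
Calliphoridae,Phormia regina,JQ246669,EF560190,JQ246718,JQ246614
Calliphoridae,Protocalliphora azurea,FR719180,,GQ409147,GQ409264
Calliphoridae,Protocalliphora sialia,KR672687,,,AJ558190
Calliphoridae,Protophormia terraenovae,JQ246670,EF560193,JQ246719,JQ246615
Calliphoridae,Sarconesia chlorogaster,JQ246674,JQ246574,JQ246723,JQ246619
Calliphoridae,Sarconesia versicolor,GQ409319,,GQ409121,
Sarcophagidae,Oxysarcodexia thornax,JQ246695,,JQ246746,
Sarcophagidae,Sarcophaga bullata,JQ246696,JQ246593,JQ246748,JQ246644
Sarcophagidae,Peckia ingens,,,JQ246747,JQ246643
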