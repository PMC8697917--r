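host_species,accession,n_examined,locality,country,report_key
Limnothrissa miodon,,24,Lake Itezhi-Tezhi,Zambia,none_itezhi
Microthrissa congica,MRAC P.98042-98135,9,Manyanga,DRC,bisthoveni_manyanga
Microthrissa congica,MRAC P.7806-7828,2,Poko,DRC,bisthoveni_poko
Microthrissa congica,MRAC P.70510-70520,2,Mobi River,DRC,bisthoveni_mobi
Microthrissa congica,MRAC P.51337-51345,1,"Inkongo, Sankuru River",DRC,bisthoveni_sankuru
Microthrissa congica,MRAC P.120555-120576,3,Kinshasa,DRC,bisthoveni_kinshasa
Microthrissa congica,NHMUK 1976.12.20.42-77,12,Lualaba River,DRC,boegeri_lualaba
Microthrissa moeruensis,MRAC 1993.145.P.0033-0064,11,Lake Mweru,Zambia,chochamandai_mweru
Microthrissa moeruensis,MRAC 1994.019.P.2022-2080,5,Kashilu,Zambia,chochamandai_kashilu
Microthrissa royauxi,MRAC 73022.P.0037-0131,11,Pool Malebo,DRC,rochetteae_malebo
Microthrissa royauxi,MRAC 88001.P.0407-0417,2,Pool Malebo,DRC,rochetteae_malebo
Nannothrissa parva,MRAC P.93560-93620,9,Lake Tumba,DRC,parisellei_tumba
Nannothrissa parva,MRAC P.100646-100655,10,Lake Tumba,DRC,parisellei_tumba_trib
Nannothrissa parva,MRAC P.430-440,2,Mbandaka,DRC,parisellei_mbandaka
Odaxothrissa mento,MRAC 1973.007.P.0019-0026,2,Lake Volta,Ghana,marispastoris_volta
Odaxothrissa mento,MRAC 93-127-P-0003-0009,1,Lake Volta,Ghana,marispastoris_volta
Odaxothrissa ansorgii,MRAC A0-048-P-1217-1261,10,Lake Nguene,Gabon,voreli_nguene
Odaxothrissa ansorgii,MRAC A1-070-P-0266,2,"Aboun, Noya River",Gabon,voreli_noya
Odaxothrissa losera,MRAC 1977.042.P.0001-0011,2,Pool Malebo,DRC,sefcae_malebo
Potamothrissa acutirostris,MRAC P.124782-124799,2,Ankoro,DRC,none_ankoro
Potamothrissa acutirostris,NHMUK 1920.5.26.3-12,10,"Kilwa, Lake Mweru",DRC,chochamandai_kilwa
Potamothrissa acutirostris,MRAC 1989.043.P.0283-0290,2,Tshopo River,DRC,none_tshopo
Potamothrissa acutirostris,MRAC P.8115-8120,1,Bosabangi,DRC,none_bosabangi
Potamothrissa obtusirostris,MRAC P.70319-70326,1,"Kindu, Lualaba River",DRC,none_kindu
Potamothrissa obtusirostris,MRAC 1989.043.P.0271-0276,1,Oso River,DRC,none_oso
Pellonula leonensis,NHMUK 1964.10.12.23-29,7,Agorkpo Creek,Ghana,hahni_agorkpo
Pellonula leonensis,MRAC 1973.005.P.0285-0373,19,Lake Volta,Ghana,hugei_volta
Pellonula leonensis,MRAC 2000.048.P.1084-1123,6,Lambarene,Ghana,verbisti_lambarene
Pellonula vorax,MRAC P.71028-71040,2,Lake Nguene,Gabon,none_nguene_vorax
Pellonula vorax,MRAC 2000.048.P.1155-1162,1,Lake Nguene,Gabon,none_nguene_vorax
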