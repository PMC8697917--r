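report_key,species,host_species,locality,country,n_examined,n_infected,worm_counts,printed_intensity,resolved
voreli_noya,K. voreli,Odaxothrissa ansorgii,"Aboun, Noya River",Gabon,2,1,1,1,TRUE
voreli_nguene,K. voreli,Odaxothrissa ansorgii,Lake Nguene,Gabon,10,4,,2,FALSE
marispastoris_volta,K. marispastoris,Odaxothrissa mento,Lake Volta,Ghana,3,1,1,1,TRUE
sefcae_malebo,K. sefcae,Odaxothrissa losera,Pool Malebo,DRC,2,2,3;16,9.5,TRUE
parisellei_tumba,K. parisellei,Nannothrissa parva,Lake Tumba,DRC,9,2,1;2,1.5,TRUE
parisellei_tumba_trib,K. parisellei,Nannothrissa parva,tributary of Lake Tumba,DRC,10,6,,,FALSE
parisellei_mbandaka,K. parisellei,Nannothrissa parva,Mbandaka,DRC,2,0,,,TRUE
hugei_volta,K. hugei,Pellonula leonensis,Lake Volta,Ghana,19,13,,,FALSE
hahni_agorkpo,K. hahni,Pellonula leonensis,Agorkpo Creek,Ghana,7,3,1;1;2,1.3,TRUE
verbisti_lambarene,K. verbisti,Pellonula leonensis,Lambarene,Ghana,6,2,2;3,2.5,TRUE
chochamandai_mweru,K. chochamandai,Microthrissa moeruensis,Lake Mweru,Zambia,11,3,1;1;1,1,TRUE
chochamandai_kilwa,K. chochamandai,Potamothrissa acutirostris,"Kilwa, Lake Mweru",DRC,10,1,1,1,TRUE
chochamandai_kashilu,K. chochamandai,Microthrissa moeruensis,Kashilu,Zambia,5,2,1;1,1,TRUE
bisthoveni_poko,K. bisthoveni,Microthrissa congica,Poko,DRC,2,1,2,2,TRUE
bisthoveni_mobi,K. bisthoveni,Microthrissa congica,Mobi River,DRC,2,1,1,1,TRUE
bisthoveni_manyanga,K. bisthoveni,Microthrissa congica,Manyanga,DRC,9,2,1;1,1,TRUE
bisthoveni_sankuru,K. bisthoveni,Microthrissa congica,"Inkongo, Sankuru River",DRC,1,0,,,TRUE
bisthoveni_kinshasa,K. bisthoveni,Microthrissa congica,Kinshasa,DRC,3,0,,,TRUE
boegeri_lualaba,K. boegeri,Microthrissa congica,Lualaba River,DRC,12,3,1;1;1,1,TRUE
rochetteae_malebo,K. rochetteae,Microthrissa royauxi,Pool Malebo,DRC,13,8,1;1;1;1;1;2;2;2,1.4,TRUE
none_itezhi,,Limnothrissa miodon,Lake Itezhi-Tezhi,Zambia,24,0,,,TRUE
none_nguene_vorax,,Pellonula vorax,Lake Nguene,Gabon,3,0,,,TRUE
none_ankoro,,Potamothrissa acutirostris,Ankoro,DRC,2,0,,,TRUE
none_tshopo,,Potamothrissa acutirostris,Tshopo River,DRC,2,0,,,TRUE
none_bosabangi,,Potamothrissa acutirostris,Bosabangi,DRC,1,0,,,TRUE
none_kindu,,Potamothrissa obtusirostris,"Kindu, Lualaba River",DRC,1,0,,,TRUE
none_oso,,Potamothrissa obtusirostris,Oso River,DRC,1,0,,,TRUE
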