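((Cyprinus_carpio:39,Sinocyclocheilus_grahami:39)cyprinids:391,((Xenopus_tropicalis:204,Rana_catesbeiana:204)anura:148,(((Python_molurus:81,(Ophiophagus_hannah:60,(Pantherophis_guttatus:45,(Crotalus_horridus:20,Protobothrops_mucrosquamatus:20)crotalines:25)colubrids:15)caenophidia:21)serpentes:199,(((Geospiza_fortis:20,Zonotrichia_albicollis:20)finches:18,(Serinus_canaria:25,Setophaga_coronata:25)canaries:13)passeroida:44,(Nestor_notabilis:45,(Amazona_aestiva:30,Agapornis_roseicollis:30)coreparrots:15)psittaciformes:37)psittacopasserae:198)sauropsida:32,(((Mus_caroli:6.5,Mus_musculus:6.5)mus:83.5,(Ursus_maritimus:50,(Odobenus_rosmarus:40,Enhydra_lutris:40)arctoidea:10)carnivora:40)boreoeutheria:70,Monodelphis_domestica:160)theria:152)amniota:40)tetrapoda:78)vertebrata;
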