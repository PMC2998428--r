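family,species,individuals,groups,transects,coral_associated_adult,algal_adult
Acanthuridae,Acanthurus grammoptilus,40,26,18,FALSE,FALSE
Acanthuridae,Acanthurus dussumieri,12,7,4,FALSE,FALSE
Apogonidae,Apogon rueppellii,128,18,8,FALSE,TRUE
Apogonidae,Apogon wassinki,332,22,20,FALSE,FALSE
Apogonidae,Cheilodipterus quinquelineatus,20,18,11,FALSE,FALSE
Blenniidae,Atrosalarias fuscus,13,10,8,FALSE,FALSE
Chaetodontidae,Chaetodon assarius,24,21,17,FALSE,FALSE
Chaetodontidae,Chaetodon auriga,6,6,5,FALSE,FALSE
Chaetodontidae,Chaetodon plebeius,116,95,55,TRUE,FALSE
Chaetodontidae,Chaetodon trifascialis,14,14,12,TRUE,FALSE
Chaetodontidae,Chaetodon trifasciatus,7,6,5,TRUE,FALSE
Labridae,Anampses geographicus,234,42,27,FALSE,FALSE
Labridae,Anampses caeruleopunctatus,11,9,9,FALSE,FALSE
Labridae,Coris aygula,6,4,4,FALSE,FALSE
Labridae,Coris caudimacula,158,66,37,FALSE,FALSE
Labridae,Cheilinus chlorourus,17,14,8,FALSE,FALSE
Labridae,Cheilinus trilobatus,59,56,33,FALSE,FALSE
Labridae,Cheilio inermis,20,10,8,FALSE,FALSE
Labridae,Gomphosus varius,12,12,11,FALSE,FALSE
Labridae,Hologymnosus annulatus,9,8,7,FALSE,FALSE
Labridae,Halichoeres marginatus,11,11,8,FALSE,FALSE
Labridae,Halichoeres nebulosus,203,132,38,FALSE,TRUE
Labridae,Hemigymnus fasciatus,8,7,7,FALSE,FALSE
Labridae,Hemigymnus melapterus,33,32,23,FALSE,FALSE
Labridae,Labrichthys unilineatus,155,97,51,TRUE,FALSE
Labridae,Labroides dimidiatus,18,16,13,FALSE,FALSE
Labridae,Macropharyngodon ornatus,35,33,23,FALSE,FALSE
Labridae,Stethojulis bandanensis,442,314,106,FALSE,FALSE
Labridae,Stethojulis interrupta,431,230,79,FALSE,FALSE
Labridae,Stethojulis strigiventer,219,92,42,FALSE,FALSE
Labridae,Thalassoma hardwicke,33,31,20,FALSE,FALSE
Labridae,Thalassoma lunare,354,243,95,FALSE,FALSE
Labridae,Thalassoma lutescens,26,25,16,FALSE,FALSE
Lethrinidae,Lethrinus atkinsoni,105,66,22,FALSE,FALSE
Monocanthidae,Oxymonacanthus longirostris,7,4,4,TRUE,FALSE
Mullidae,Parupeneus barberinoides,47,28,18,FALSE,FALSE
Mullidae,Parupeneus spilurus,149,49,32,FALSE,FALSE
Nemipteridae,Scolopsis bilineatus,7,7,6,FALSE,FALSE
Pomacentridae,Chromis viridis,447,29,22,TRUE,FALSE
Pomacentridae,Dascyllus aruanus,213,101,52,TRUE,FALSE
Pomacentridae,Dascyllus reticulatus,109,47,30,TRUE,FALSE
Pomacentridae,Dascyllus trimaculatus,21,8,8,TRUE,FALSE
Pomacentridae,Dischistodus perspicillatus,5,4,4,FALSE,FALSE
Pomacentridae,Dischistodus prosopotaenia,8,8,4,FALSE,FALSE
Pomacentridae,Neoglyphidodon melas,26,20,14,FALSE,FALSE
Pomacentridae,Pomacentrus coelestis,748,182,69,FALSE,FALSE
Pomacentridae,Pomacentrus moluccensis,632,324,94,TRUE,FALSE
Pomacentridae,Pomacentrus vaiuli,60,59,29,FALSE,FALSE
Pomacentridae,Plectroglyphidodon lacrymatus,55,51,37,FALSE,FALSE
Pomacentridae,Stegastes nigricans,10,8,6,FALSE,FALSE
Pomacentridae,Stegastes obreptus,10,10,9,FALSE,FALSE
Scaridae,Chlorurus microrhinos,26,22,18,FALSE,FALSE
Scaridae,Chlorurus sordidus,516,226,85,FALSE,FALSE
Scaridae,Leptoscarus vaigiensis,410,91,40,FALSE,TRUE
Scaridae,Scarus frenatus,71,49,35,FALSE,FALSE
Scaridae,Scarus prasiognathos,91,68,44,FALSE,FALSE
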