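taxon,specimen,clade,humerus_mm,estimated
Brachylophosaurus canadensis,MOR 794,Saurolophinae,595,FALSE
Edmontosaurus regalis,CMN 8399,Saurolophinae,623,FALSE
Edmontosaurus regalis,ROM 801,Saurolophinae,674,FALSE
Edmontosaurus annectens,SM R4036,Saurolophinae,520,FALSE
Edmontosaurus annectens,YPM 2182,Saurolophinae,560,FALSE
Gryposaurus notabilis,ROM 764,Saurolophinae,600,FALSE
Gryposaurus notabilis,MSNM V345,Saurolophinae,705,FALSE
Prosaurolophus maximus,ROM 787,Saurolophinae,532,FALSE
Saurolophus osborni,AMNH 5220,Saurolophinae,600,FALSE
Shantungosaurus giganteus,GMV 1780,Saurolophinae,915,FALSE
Magnapaulia laticaudus,LACM 17712,Lambeosaurinae,803,TRUE
Magnapaulia laticaudus,LACM 17716,Lambeosaurinae,650,FALSE
Magnapaulia laticaudus,LACM 17715,Lambeosaurinae,600,FALSE
cf Parasaurolophus,AMNH 5893,Lambeosaurinae,600,FALSE
Tsintaosaurus spinorhinus,IVPP V725,Lambeosaurinae,568,FALSE
Parasaurolophus cyrtocristatus,FMNH P27393,Lambeosaurinae,565,FALSE
Olorotitan arharensis,AEHM 2/845,Lambeosaurinae,540,FALSE
Lambeosaurinae indeterminate,FMNH UC1479,Lambeosaurinae,502,FALSE
Parasaurolophus walkeri,ROM 768,Lambeosaurinae,520,FALSE
Hypacrosaurus altispinus,CMN 8501,Lambeosaurinae,530,FALSE
Corythosaurus casuarius,ROM 845,Lambeosaurinae,430,FALSE
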