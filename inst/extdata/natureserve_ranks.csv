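species_code,family,natureserve_rank
Papilio polyxenes,Papilionidae,G5
Papilio cresphontes,Papilionidae,G5
Papilio glaucus,Papilionidae,G5
Papilio troilus,Papilionidae,G4
Pontia protodice,Pieridae,G5
Pieris rapae,Pieridae,G5
Euchloe olympia,Pieridae,G5
Colias philodice,Pieridae,G5
Colias eurytheme,Pieridae,G5
Phoebis sennae,Pieridae,G5
Eurema lisa,Pieridae,G5
Lycaena phlaeas,Lycaenidae,G5
Lycaena hyllus,Lycaenidae,G5
Satyrium titus,Lycaenidae,G5
Satyrium edwardsii,Lycaenidae,G5
Satyrium calanus,Lycaenidae,G5
Satyrium liparops,Lycaenidae,G5
Strymon melinus,Lycaenidae,G5
Everes comyntas,Lycaenidae,G5
Celastrina ladon,Lycaenidae,G4G5
Lycaeides melissa samuelis,Lycaenidae,G5T2
Euptoieta claudia,Nymphalidae,G5
Speyeria cybele,Nymphalidae,G5
Speyeria aphrodite,Nymphalidae,G5
Phyciodes spp.,Nymphalidae,G5
Polygonia interrogationis,Nymphalidae,G5
Polygonia comma,Nymphalidae,G5
Nymphalis antiopa,Nymphalidae,G5
Vanessa virginiensis,Nymphalidae,G5
Vanessa atalanta,Nymphalidae,G5
Junonia coenia,Nymphalidae,G5
Limenitis arthemis astyanax,Nymphalidae,G5
Limenitis archippus,Nymphalidae,G5
Enodia anthedon,Nymphalidae,G5
Satyrodes appalachia,Nymphalidae,G4
Megisto cymela (includes viola),Nymphalidae,G5
Cercyonis pegala,Nymphalidae,G5
Danaus plexippus,Nymphalidae,G4T1
Epargyreus clarus,Hesperiidae,G5
Thorybes bathyllus,Hesperiidae,G5
Thorybes pylades,Hesperiidae,G5
Staphylus hayhurstii,Hesperiidae,G5
Erynnis icelus,Hesperiidae,G5
Erynnis brizo,Hesperiidae,G5
Erynnis juvenalis,Hesperiidae,G5
Erynnis horatius,Hesperiidae,G5
Erynnis martialis,Hesperiidae,G3
Erynnis baptisiae,Hesperiidae,G5
Thymelicus lineola,Hesperiidae,G5
Hylephila phyleus,Hesperiidae,G5
Hesperia leonardus,Hesperiidae,G5
Polites peckius,Hesperiidae,G5
Polites themistocles,Hesperiidae,G5
Polites origenes,Hesperiidae,G4G5
Wallengrenia egeremet,Hesperiidae,G5
Anatrytone logan,Hesperiidae,G5
Problema byssus,Hesperiidae,G3G4
Poanes hobomok,Hesperiidae,G5
Euphyes vestris,Hesperiidae,G5
Atrytonopsis hianna,Hesperiidae,G4G5
Amblyscirtes vialis,Hesperiidae,G5
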