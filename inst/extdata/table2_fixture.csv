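family,common_name,species_name,mean_density,density_se,density_rank,counts,max_group,max_group_significance,esw,esw_pooled
Papilionidae,Black Swallowtail,Papilio polyxenes,0.115,0.051,39,36,Open,*,5.98,TRUE
Papilionidae,Giant Swallowtail,Papilio cresphontes,0.008,0.006,58,3,Savanna,,5.98,TRUE
Papilionidae,Eastern Tiger Swallowtail,Papilio glaucus,0.684,0.090,18,215,Woodland,,5.98,TRUE
Papilionidae,Spicebush Swallowtail,Papilio troilus,2.554,0.465,8,802,Forest,,5.98,TRUE
Pieridae,Checkered White,Pontia protodice,0.071,0.046,47,28,Scrub,,7.62,TRUE
Pieridae,Cabbage White,Pieris rapae,1.016,0.252,14,250,Open,,4.68,FALSE
Pieridae,Olympia Marble,Euchloe olympia,0.078,0.029,46,31,Open,,7.62,TRUE
Pieridae,Clouded Sulphur,Colias philodice,0.304,0.141,28,100,Open,***,6.26,FALSE
Pieridae,Orange Sulphur,Colias eurytheme,1.188,0.500,13,530,Open,*,8.5,FALSE
Pieridae,Cloudless Sulphur,Phoebis sennae,0.023,0.016,53,10,Scrub,,8.5,FALSE
Pieridae,Little Yellow,Eurema lisa,6.382,2.789,5,624,Woodland,,1.86,FALSE
Lycaenidae,American Copper,Lycaena phlaeas,0.302,0.252,29,43,Open,,2.72,TRUE
Lycaenidae,Bronze Copper,Lycaena hyllus,0.021,0.021,55,3,Open,,2.72,TRUE
Lycaenidae,Coral Hairstreak,Satyrium titus,0.236,0.128,32,22,Savanna,,1.78,TRUE
Lycaenidae,Edwards' Hairstreak,Satyrium edwardsii,1.538,0.538,12,146,Scrub,,1.81,FALSE
Lycaenidae,Banded Hairstreak,Satyrium calanus,0.086,0.048,44,8,Scrub,,1.78,TRUE
Lycaenidae,Striped Hairstreak,Satyrium liparops,0.011,0.011,57,1,Open,,1.78,TRUE
Lycaenidae,Gray Hairstreak,Strymon melinus,0.227,0.113,34,21,Woodland,,1.78,TRUE
Lycaenidae,Eastern Tailed Blue,Everes comyntas,1.879,0.483,9,195,Open,,1.97,FALSE
Lycaenidae,Spring Azure,Celastrina ladon,4.265,1.824,6,470,Scrub,,2.1,FALSE
Lycaenidae,Karner Blue,Lycaeides melissa samuelis,9.262,4.949,2,1124,Savanna,,2.31,FALSE
Nymphalidae,Variegated Fritillary,Euptoieta claudia,0.044,0.026,51,8,Open,,3.33,TRUE
Nymphalidae,Great Spangled Fritillary,Speyeria cybele,2.581,0.496,7,559,Savanna,,4.13,FALSE
Nymphalidae,Aphrodite Fritillary,Speyeria aphrodite,0.124,0.058,38,22,Woodland,,3.33,TRUE
Nymphalidae,Phyciodes spp.,Phyciodes spp.,1.796,0.385,10,249,Scrub,,2.64,FALSE
Nymphalidae,Question Mark,Polygonia interrogationis,0.961,0.168,15,48,Open,,0.96,TRUE
Nymphalidae,Eastern Comma,Polygonia comma,0.179,0.070,37,9,Woodland,,0.96,TRUE
Nymphalidae,Mourning Cloak,Nymphalis antiopa,0.385,0.137,24,19,Savanna,,0.96,TRUE
Nymphalidae,American Lady,Vanessa virginiensis,0.661,0.153,19,88,Woodland,,2.54,FALSE
Nymphalidae,Red Admiral,Vanessa atalanta,0.828,0.203,17,57,Savanna,,1.32,FALSE
Nymphalidae,Common Buckeye,Junonia coenia,0.374,0.100,25,60,Open,***,3.07,FALSE
Nymphalidae,Red-spotted Purple,Limenitis arthemis astyanax,0.210,0.042,35,55,Scrub,,4.94,FALSE
Nymphalidae,Viceroy,Limenitis archippus,1.700,0.511,11,296,Open,,3.32,FALSE
Nymphalidae,Northern Pearly-Eye,Enodia anthedon,0.007,0.007,61,1,Forest,,2.81,FALSE
Nymphalidae,Appalachian Brown,Satyrodes appalachia,0.580,0.241,21,86,Savanna,,2.81,FALSE
Nymphalidae,Little Wood Satyr,Megisto cymela (includes viola),14.901,2.621,1,1730,Savanna,,2.21,FALSE
Nymphalidae,Common Wood-Nymph,Cercyonis pegala,8.097,1.469,3,765,Scrub,,1.8,FALSE
Nymphalidae,Monarch,Danaus plexippus,0.904,0.289,16,341,Open,,7.19,FALSE
Hesperiidae,Silver-spotted Skipper,Epargyreus clarus,7.131,1.852,4,408,Open,,1.09,FALSE
Hesperiidae,Southern Cloudywing,Thorybes bathyllus,0.240,0.094,31,29,Open,,2.31,TRUE
Hesperiidae,Northern Cloudywing,Thorybes pylades,0.083,0.034,45,10,Savanna,,2.31,TRUE
Hesperiidae,Hayhurst's Scallopwing,Staphylus hayhurstii,0.008,0.008,58,1,Forest,,2.31,TRUE
Hesperiidae,Dreamy Duskywing,Erynnis icelus,0.023,0.016,53,3,Open,,2.31,TRUE
Hesperiidae,Sleepy Duskywing,Erynnis brizo,0.550,0.273,22,57,Open,,1.98,FALSE
Hesperiidae,Juvenal's Duskywing,Erynnis juvenalis,0.105,0.068,40,13,Woodland,,2.31,TRUE
Hesperiidae,Horace's Duskywing,Erynnis horatius,0.340,0.141,26,41,Woodland,,2.31,TRUE
Hesperiidae,Mottled Duskywing,Erynnis martialis,0.628,0.582,20,77,Scrub,,2.32,FALSE
Hesperiidae,Wild Indigo Duskywing,Erynnis baptisiae,0.230,0.122,33,60,Open,,4.94,FALSE
Hesperiidae,European Skipper,Thymelicus lineola,0.039,0.023,52,5,Open,,2.45,TRUE
Hesperiidae,Fiery Skipper,Hylephila phyleus,0.049,0.034,49,6,Scrub,,2.45,TRUE
Hesperiidae,Leonard's Skipper,Hesperia leonardus,0.196,0.101,36,25,Open,,2.45,TRUE
Hesperiidae,Peck's Skipper,Polites peckius,0.089,0.063,43,11,Open,,2.45,TRUE
Hesperiidae,Tawny-edged Skipper,Polites themistocles,0.070,0.034,48,9,Open,,2.45,TRUE
Hesperiidae,Crossline Skipper,Polites origenes,0.447,0.122,23,123,Scrub,,5.25,FALSE
Hesperiidae,Northern Broken Dash,Wallengrenia egeremet,0.311,0.079,27,40,Open,,2.45,TRUE
Hesperiidae,Delaware Skipper,Anatrytone logan,0.105,0.051,40,13,Open,,2.45,TRUE
Hesperiidae,Byssus Skipper,Problema byssus,0.012,0.012,56,2,Open,,2.45,TRUE
Hesperiidae,Hobomok Skipper,Poanes hobomok,0.259,0.082,30,33,Savanna,,2.45,TRUE
Hesperiidae,Dun Skipper,Euphyes vestris,0.008,0.008,58,1,Woodland,,2.45,TRUE
Hesperiidae,Dusted Skipper,Atrytonopsis hianna,0.099,0.078,42,13,Open,,2.45,TRUE
Hesperiidae,Common Roadside-Skipper,Amblyscirtes vialis,0.047,0.026,50,6,Open,,2.45,TRUE
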