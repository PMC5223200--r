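Lectin	Specificity	Ratio
PSA	Fucα-1,6GlcNAc, α-D-Man, α-D-Glc	2.35
WFA	terminating in GalNAcα/β1-3/6 Gal	0.61
PTL-I	GalNAc, GalNAcα-1,3 Gal, GalNAcα-1,3Galβ-1,3/4Glc	0.22
AAL	Fucα1-6 GlcNAc(core fucose), Fucα1-3(Galβ1-4)GlcNAc	0.42
PTL-II	Gal, blood group H, T-antigen	0.61
SBA	α- or β-linked terminal GalNAc, (GalNAc)n, GalNAcα1-3 Gal	0.57
UEA-I	Fucα1-2Galβ1-4Glc(NAc)	0.53
PHA-E + L	Bisecting GlcNAc, bi-antennary N-glycans, tri- and tetra-antennary complex-type N-glycan	0.34
SNA	Sia2-6Gal/GalNAc	0.62
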