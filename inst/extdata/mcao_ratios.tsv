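Lectin	Specificity	Ratio_M16_MC	Ratio_M48_MC
ECA	Galβ-1,4GlcNAc (type II), Galβ1-3GlcNAc (type I)	1.99	2.20
WFA	terminating in GalNAcα/β1-3/6 Gal	2.54	2.17
PTL-I	GalNAc, GalNAcα-1,3 Gal, GalNAcα-1,3Galβ-1,3/4Glc	2.66	1.74
LCA	α-D-Man, Fucα-1,6GlcNAc, α-D-Glc	2.24	2.37
VVA	terminal GalNAc, GalNAcα-Ser/Thr(Tn), GalNAcα1-3 Gal	1.93	1.75
GNA	High-Mannose, Manα1-3Man	1.94	2.67
PHA-E + L	Bisecting GlcNAc, bi-antennary N-glycans, tri- and tetra-antennary complex-type N-glycan	1.68	1.94
DBA	αGalNAc, Tn antigen, GalNAcα1-3((Fucα1-2))Gal (blood group A antigen)	1.39	1.58
PTL-II	Gal, blood group H, T-antigen	1.35	1.84
NPA	High-Mannose, Manα1-6Man	1.43	1.69
SNA	Sia2-6Gal/GalNAc	1.47	1.60
SJA	Terminal in GalNAc and Gal	0.40	0.33
GLS-I	αGalNAc, αGal, anti-A and B	0.58	0.77
STL	trimers and tetramers of GlcNAc, core (GlcNAc) of N-glycan, oligosaccharide containing GlcNAc and MurNAc	0.46	0.54
ConA	High-Mannose, Manα1-6(Manα1-3)Man, αMannose, αGlc	0.45	0.45
BPL	Galβ1-3GalNAc, Terminal GalNAc	0.55	0.52
PHA-E	Bisecting GlcNAc, biantennary complex-type N-glycan with outer Gal	0.74	0.64
LEL	(GlcNAc)n, high mannose-type N-glycans	0.70	0.53
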