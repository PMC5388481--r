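locus	species	d_intra	nearest_species	d_nn
matK	Anthosachne scabra	0.9	Rytidosperma pallidum	0.38
matK	Austrostipa densiflora	0.12	Nassella trichotoma	1.43
matK	Eragrostis curvula	1.28	Hyparrhenia hirta	4.49
matK	Hyparrhenia hirta	0.56	Eragrostis curvula	4.49
matK	Microlaena stipoides	1.28	Austrostipa densiflora	6.21
matK	Nassella neesiana	0.66	Nassella trichotoma	0.11
matK	Nassella trichotoma	0.97	Nassella neesiana	0.11
matK	Poa sieberiana	0.45	Anthosachne scabra	4.84
matK	Rytidosperma caespitosum	9.71	Rytidosperma pallidum	0
matK	Rytidosperma pallidum	9.45	Rytidosperma caespitosum	0
matK	Themeda triandra	6.47	Rytidosperma pallidum	0
ETS	Austrostipa densiflora	0.77	Nassella neesiana	7.09
ETS	Chloris gayana	0	Hyparrhenia hirta	27.31
ETS	Hyparrhenia hirta	0.7	Chloris gayana	27.31
ETS	Nassella neesiana	0.21	Nassella trichotoma	2.92
ETS	Nassella trichotoma	0.21	Nassella neesiana	2.92
ITS	Chloris gayana	0.87	Eragrostis curvula	16.74
ITS	Eragrostis curvula	5.21	Chloris gayana	16.74
ITS	Nassella trichotoma	N/A	Eragrostis curvula	20.7
atpF	Anthosachne scabra	0.25	Austrostipa densiflora	2.7
atpF	Austrostipa densiflora	0.2	Nassella trichotoma	0.22
atpF	Chloris gayana	0	Eragrostis curvula	3.03
atpF	Eragrostis curvula	5.8	Chloris gayana	3.03
atpF	Hyparrhenia hirta	0.38	Eragrostis curvula	4.73
atpF	Microlaena stipoides	0.63	Nassella neesiana	4.34
atpF	Nassella neesiana	1.05	Nassella trichotoma	0
atpF	Nassella trichotoma	0.48	Nassella neesiana	0
atpF	Poa sieberiana	0	Themeda triandra	2.45
atpF	Rytidosperma caespitosum	0.83	Rytidosperma pallidum	0.9
atpF	Rytidosperma pallidum	1.38	Rytidosperma caespitosum	0.9
atpF	Themeda triandra	0	Poa sieberiana	2.45
ndhK	Anthosachne scabra	N/A	Austrostipa densiflora	2.13
ndhK	Austrostipa densiflora	0	Nassella neesiana	0.26
ndhK	Chloris gayana	N/A	Eragrostis curvula	2.53
ndhK	Eragrostis curvula	2.79	Chloris gayana	2.53
ndhK	Hyparrhenia hirta	0.75	Eragrostis curvula	3.2
ndhK	Microlaena stipoides	0.82	Eragrostis curvula	3.37
ndhK	Nassella neesiana	2.83	Nassella trichotoma	0
ndhK	Nassella trichotoma	4.85	Nassella neesiana	0
psbE	Anthosachne scabra	0.47	Nassella neesiana	42.41
psbE	Eragrostis curvula	0.63	Hyparrhenia hirta	5.16
psbE	Hyparrhenia hirta	1.16	Eragrostis curvula	5.16
psbE	Nassella neesiana	2.07	Nassella trichotoma	0
psbE	Nassella trichotoma	0.29	Nassella neesiana	0
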