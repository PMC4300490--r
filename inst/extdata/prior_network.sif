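# Synthetic protein-level prior-knowledge network of the yeast HOG and
# pheromone MAPK pathways (reconstruction assembled for this package from
# the pathway wiring described in the literature; see the methods
# vignette for provenance).  Relation 1 = activation, -1 = inhibition.
NaCl 1 Sln1
NaCl 1 Sho1
NaCl -1 Ypk1
Phe 1 Ste2
Phe 1 Bit61
Sln1 -1 Ssk1
Ssk1 1 Ssk2
Ssk1 1 Ssk22
Ssk2 1 Pbs2
Ssk22 1 Pbs2
Sho1 1 Ste20
Cdc42 1 Ste20
Ste4 1 Ste20
Ste20 1 Ste11
Ste11 1 Ste11_Ste50_complex
Ste50 1 Ste11_Ste50_complex
Ste11_Ste50_complex 1 Pbs2
Pbs2 1 Hog1
Pbs2 1 Nbp2
Nbp2 1 Ptc1
Ptc1 -1 Hog1
Ptp2 -1 Hog1
Hog1 1 Hot1
Hog1 1 Sko1
Hog1 1 Rck2
Hog1 1 Msn2
Hog1 1 Msn4
Hog1 -1 Ste50
Ste2 1 Gpa1
Gpa1 1 Ste4
Ste4 1 Cdc42
Ste4 1 Ste5
Ste5 1 Ste7
Ste7 1 Fus3
Fus3 1 Ste12
Fus3 1 Far1
Fus3 1 Dig1
Fus3 1 Dig2
Dig1 -1 Ste12
Bit61 1 Ypk1
Bit61 1 Ypk2
Ypk1 1 Gpd1
Ypk2 1 Gpd1
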