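# schema_version=1
# Three-group partitions of the 20 standard amino acids for eight
# physicochemical properties, as used by the classical 188D global protein
# sequence descriptor (CTD) family. group labels: g1/g2/g3 in the
# conventional low/middle/high (or polar/neutral/hydrophobic etc.) order.
property	group	residues
hydrophobicity	g1	RKEDQN
hydrophobicity	g2	GASTPHY
hydrophobicity	g3	CLVIMFW
vdw_volume	g1	GASTPDC
vdw_volume	g2	NVEQIL
vdw_volume	g3	MHKFRYW
polarity	g1	LIFWCMVY
polarity	g2	PATGS
polarity	g3	HQRKNED
polarizability	g1	GASDT
polarizability	g2	CPNVEQIL
polarizability	g3	KMHFRYW
charge	g1	KR
charge	g2	ANCQGHILMFPSTWYV
charge	g3	DE
surface_tension	g1	GQDNAHR
surface_tension	g2	KTSEC
surface_tension	g3	ILMFPWYV
secondary_structure	g1	EALMQKRH
secondary_structure	g2	VIYCWFT
secondary_structure	g3	GNPSD
solvent_accessibility	g1	ALFCGIVW
solvent_accessibility	g2	RKQEND
solvent_accessibility	g3	MSPTHY
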