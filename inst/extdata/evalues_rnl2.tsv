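family	name	DpRNL	NgRNL	TbREL1	TbREL2
PF01068	DNA ligase (ATP dependent)	3.30e-5	2.60e-5	1.00e-3	1.60e-6
PF01653	DNA ligase (NAD dependent)	2.20e-2	2.90e-2	-	4.70e-1
PF09511	RNA ligase Rnl1 (defense, splicing)	2.70e-1	1.30e-2	3.40e-1	4.00e-1
PF09414	RNA ligase Rnl2 (editing)	4.90e-12	3.20e-9	7.90e-55	4.30e-53
PF01331	Capping enzyme	2.70e-1	1.70e-1	9.10e-3	2.10e-1
PF02834	LigT	-	-	-	-
PF01139	RtcB (splicing)	-	-	4.80e-1	-
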