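accession	gene	protein_name	cellular_component	avg_sc	single_peptide	detected_in
Q92686	NRGN	Neurogranin	Membrane; Cytoplasm	15	FALSE	scd
Q96KN2	CNDP1	Beta-Ala-His dipeptidase	Secreted	7.25	FALSE	scd
Q99884	SLC6A7	Sodium-dependent proline transporter	Membrane	6	FALSE	scd
P01213	PDYN	Beta-neoendorphin-dynorphin	Secreted	2	FALSE	scd
P56975	NRG3	Pro-neuregulin-3, membrane-bound isoform	Membrane	2	FALSE	scd
P14136	GFAP	Glial fibrillary acidic protein	Cytoplasm	2	FALSE	scd
O94933	SLITRK3	SLIT and NTRK-like protein 3	Membrane	2	FALSE	scd
P08908	HTR1A	5-hydroxytryptamine receptor 1A	Membrane	1	TRUE	scd
A7E2E4	DPP6	Dipeptidyl-peptidase 6	Membrane	1	TRUE	scd
Q96FT7	ASIC4	Amiloride-sensitive cation channel 4	Membrane	1	TRUE	scd
B3KXG7	PTPN5	Protein tyrosine phosphatase, non-receptor type 5	Endoplasmic reticulum membrane	1	TRUE	scd
Q9P218	COL20A1	Collagen alpha-1(XX)	Secreted	1	TRUE	scd
O95741	CPNE6	Copine-6	Mitochondrion	1	TRUE	scd
Q9UI47	CTNNA3	Catenin alpha-3	Cytoplasm	1	TRUE	scd
P51674	GPM6A	Neuronal membrane glycoprotein M6-a	Membrane	1	TRUE	scd
Q9UQM7	CAMK2A	Calcium/calmodulin-dependent protein kinase type II subunit alpha	Membrane	1	TRUE	scd
Q96NJ5	KLHL32	Kelch-like protein 32	Unknown	1	TRUE	scd
Q8N967	LRTM2	Leucine-rich repeat and transmembrane domain-containing protein 2	Membrane	1	TRUE	scd
Q96NK8	NEUROD6	Neurogenic differentiation factor 6	Nucleus	1	TRUE	scd
Q8N987	NECAB1	N-terminal EF-hand calcium-binding protein 1	Cytoplasm	1	TRUE	scd
Q13516	OLIG2	Oligodendrocyte transcription factor 2	Nucleus; Cytoplasm	1	TRUE	scd
Q59GK5	GRM4	Glutamate receptor, metabotropic 4 variant	Membrane	1	TRUE	scd
Q16650	TBR1	T-box brain protein 1	Nucleus	1	TRUE	scd
Q504Y0	SLC39A12	Zinc transporter ZIP12	Membrane	1	TRUE	scd
P41225	SOX3	Transcription factor SOX-3	Nucleus	1	TRUE	scd
O75096	LRP4	Low density lipoprotein receptor-related protein 4	Membrane	1	TRUE	control
Q9Y2J0	RPH3A	Rabphilin	Cytoplasm	1	TRUE	control
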