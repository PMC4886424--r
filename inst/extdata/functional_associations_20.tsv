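# Curated reference set: 20 probable functional associations recognised for
# potential nucleotide cyclases by conserved-gene-neighborhood analysis
# intersected with domains co-occurring with the cyclase domain
# (Rosetta-stone evidence). One row per (query gene, partner gene, domain).
uniprot_id	gene_name	partner_locus	partner_pfam	partner_domain_name	function_category
R4MJ84	J113_17860	J113_17870	PF00027	Cyclic nucleotide-binding domain	Signal transduction, regulatory processes
R4MJ84	J113_17860	J113_17875	PF00027	Cyclic nucleotide-binding domain	Signal transduction, regulatory processes
J9WHW1	MIP_02960	MIP_02970	PF13458	Periplasmic binding protein	Signal transduction, transport
J9WHW1	MIP_02960	MIP_02959	PF12697	Alpha/beta hydrolase domain	Metabolic processes
U5WU67	MKAN_22035	MKAN_22050	PF12697	Alpha/beta hydrolase domain	Metabolic processes
B2HFJ8	MMAR_1384	MMAR_1388	PF12697	Alpha/beta hydrolase domain	Metabolic processes
B2HFJ8	MMAR_1384	MMAR_1378	PF01381	Helix-turn-helix domain	Regulatory processes
P9WL98	MT2638	MT2640	PF00027	Cyclic nucleotide-binding domain	Signal transduction, regulatory processes
P9WL98	MT2638	MT2641	PF00027	Cyclic nucleotide-binding domain	Signal transduction, regulatory processes
A0PR68	MUL_2491	MUL_2488	PF12697	Alpha/beta hydrolase domain	Metabolic processes
A0PR68	MUL_2491	MUL_2497	PF01381	Helix-turn-helix domain	Regulatory processes
L7V7X7	MULP_01555	MULP_01559	PF12697	Alpha/beta hydrolase domain	Metabolic processes
L7V7X7	MULP_01555	MULP_01549	PF01381	Helix-turn-helix domain	Regulatory processes
H8ITY9	OCU_21180	OCU_21250	PF13458	Periplasmic binding protein	Signal transduction, transport
H8ITY9	OCU_21180	OCU_21170	PF12697	Alpha/beta hydrolase domain	Metabolic processes
S4Z758	OEM_18810	OEM_18800	PF12697	Alpha/beta hydrolase domain	Metabolic processes
P9WL99	Rv2561	Rv2564	PF00027	Cyclic nucleotide-binding domain	Signal transduction, regulatory processes
P9WL99	Rv2561	Rv2565	PF00027	Cyclic nucleotide-binding domain	Signal transduction, regulatory processes
I2ACB6	W7S_09825	W7S_09820	PF12697	Alpha/beta hydrolase domain	Metabolic processes
W8FCI6	HSW_3800	HSW_3799	PF01966	Phosphohydrolase	Nucleic acid metabolism, signal transduction
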