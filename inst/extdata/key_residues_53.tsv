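# Curated reference set: 53 uncharacterised bacterial proteins with key
# catalytic residues (metal-binding MB, substrate-specifying SS,
# transition-state/stabilising TS) and the predicted cyclase class.
# single_aspartate marks entries with only one conserved metal-binding Asp.
uniprot_id	length	lineage	mb	ss	ts	predicted	single_aspartate
A0A023BRE9	362	Bacteroidetes	D,D	E,K	H,R	GC	FALSE
A0A024K0K6	242	Actinobacteria	D,D	E,K	H,R	GC	FALSE
A0A049E877	242	Actinobacteria	D,D	K,E	R	AC/GC	FALSE
A0A051TVK8	242	Actinobacteria	D,D	K,E	R	AC/GC	FALSE
A0A077KSK0	184	Bacteroidetes	D,D	E,K	H,Q	GC	FALSE
A0A077XT73	217	Bacteroidetes	D,D	E,K	H,R	GC	FALSE
A0A0A1S331	184	Bacteroidetes	D,D	E,K	H,Q	GC	FALSE
A0A0D3LAF1	210	Bacteroidetes	D,D	E,K	H,Y	GC	FALSE
A0A0D3LE21	204	Bacteroidetes	D,D	E,R	H,R	GC	FALSE
A0A0E0YUB2	245	Actinobacteria	D,D	K,E	R	AC/GC	FALSE
A0PR68	213	Actinobacteria	D	K,E	R	AC/GC	TRUE
A2VKS0	245	Actinobacteria	D,D	K,E	R	AC/GC	FALSE
A3XLF9	209	Bacteroidetes	D,D	E,K	H,R	GC	FALSE
A4AND1	360	Bacteroidetes	D,D	E,K	H,R	GC	FALSE
B2HFJ8	244	Actinobacteria	D,D	K,E	R	AC/GC	FALSE
C6VRW6	359	Bacteroidetes	D,D	E,K	H,Q	GC	FALSE
C7PDP1	360	Bacteroidetes	D,D	E,K	H,Q	GC	FALSE
D5B9L7	192	Bacteroidetes	D,D	E,K	H,R	GC	FALSE
D5BA05	215	Bacteroidetes	D,D	E,K	H,H	GC	FALSE
D5BC46	217	Bacteroidetes	D,D	E,K	H,Q	GC	FALSE
D5P7L7	242	Actinobacteria	D,D	K,E	R	AC/GC	FALSE
D6FJC9	245	Actinobacteria	D,D	K,E	R	AC/GC	FALSE
D7W7Q4	183	Bacteroidetes	D,D	E,K	H,Q	GC	FALSE
E3FM84	240	Proteobacteria	D,D	K,E	R	AC/GC	FALSE
F8C8H4	241	Proteobacteria	D,D	K,E	R	AC/GC	FALSE
G0IYZ8	370	Bacteroidetes	D,D	E,K	H,R	GC	FALSE
H8ITY9	242	Actinobacteria	D,D	K,E	R	AC/GC	FALSE
H8MLI0	243	Proteobacteria	D,D	K,E	R	AC/GC	FALSE
I2ACB6	242	Actinobacteria	D,D	K,E	R	AC/GC	FALSE
I4EWW4	239	Actinobacteria	D,D	E,K	H,R	GC	FALSE
J1KMR1	196	Bacteroidetes	D,D	E,K	H,C	GC	FALSE
J3CNM3	188	Bacteroidetes	D,D	E,K	H,Q	GC	FALSE
J4JVX3	242	Actinobacteria	D,D	K,E	R	AC/GC	FALSE
L7U9J7	249	Proteobacteria	D,D	K,E	R	AC/GC	FALSE
L7V7X7	244	Actinobacteria	D,D	K,E	R	AC/GC	FALSE
M7NQG3	205	Bacteroidetes	D,D	E,R	H,R	GC	FALSE
P9WL99	212	Actinobacteria	D	K,E	R	AC/GC	TRUE
Q1DBS3	241	Proteobacteria	D,D	K,E	R	AC/GC	FALSE
R4MJ84	245	Actinobacteria	D,D	K,E	R	AC/GC	FALSE
S7VP22	364	Bacteroidetes	D,D	E,K	H,R	GC	FALSE
T0P495	189	Bacteroidetes	D,D	E,K	H,R	GC	FALSE
U1IMS0	385	Proteobacteria	D,D	K,E	R	AC/GC	FALSE
U2U286	241	Proteobacteria	D,D	K,E	R	AC/GC	FALSE
U5WU67	242	Actinobacteria	D,D	K,E	R	AC/GC	FALSE
V7J481	242	Actinobacteria	D,D	K,E	R	AC/GC	FALSE
W4HRV4	242	Actinobacteria	D,D	K,E	R	AC/GC	FALSE
W4M0R9	361	Proteobacteria	D,D	E,K	H,R	GC	FALSE
W4T6K0	183	Bacteroidetes	D,D	E,K	H,Q	GC	FALSE
W6TY48	354	Bacteroidetes	D,D	E,K	H,Q	GC	FALSE
W8FCI6	383	Bacteroidetes	D,D	E,K	H,R	GC	FALSE
X7T6Z9	242	Actinobacteria	D,D	K,E	R	AC/GC	FALSE
X7YDH7	236	Actinobacteria	D,D	K,E	R	AC/GC	FALSE
X7YQD0	242	Actinobacteria	D,D	K,E	R	AC/GC	FALSE
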