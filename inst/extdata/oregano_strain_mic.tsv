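compartment	strain_id	genus	gram	streptomycin	tetracycline	ciprofloxacin	kanamycin	chloramphenicol	rifampicin
T	OVT1	Agrobacterium	negative	>50	2.5	<0.5	50	25	10
T	OVT8	Agrobacterium	negative	>50	2.5	<0.5	50	25	10
T	OVT17	Agrobacterium	negative	>50	2.5	<0.5	50	25	10
T	OVT2	Agromyces	positive	>50	>25	50	>50	10	<5
S	OVS8	Arthrobacter	positive	<0.5	<0.5	5	50	<1	<5
S	OVS18	Arthrobacter	positive	<0.5	<0.5	5	>50	<1	<5
S	OVS23	Arthrobacter	positive	<0.5	1.25	2.5	50	<1	<5
L	OVL1	Arthrobacter	positive	>50	<0.5	10	>50	<1	<5
L	OVL3	Arthrobacter	positive	50	<0.5	5	>50	<1	<5
L	OVL4	Arthrobacter	positive	50	<0.5	2.5	>50	<1	<5
L	OVL20	Arthrobacter	positive	50	<0.5	5	>50	<1	<5
L	OVL22	Arthrobacter	positive	50	<0.5	5	>50	<1	<5
T	OVT23	Arthrobacter	positive	50	<0.5	5	>50	2.5	<5
L	OVL7	Bacillus	positive	<0.5	<0.5	<0.5	<0.5	2.5	<5
L	OVL8	Bacillus	positive	5.0	<0.5	<0.5	1	5	<5
S	OVS6	Bacillus	positive	<0.5	<0.5	<0.5	<0.5	10	<5
S	OVS10	Bacillus	positive	<0.5	2.5	<0.5	<0.5	2.5	<5
S	OVS21	Bacillus	positive	<0.5	2.5	<0.5	<0.5	2.5	<5
F	OVF22	Bacillus	positive	2.5	2.5	<0.5	<0.5	<1	<5
L	OVL9	Bacillus	positive	2.5	1.25	<0.5	1	<1	<5
S	OVS26	Bacillus	positive	2.5	1.25	<0.5	2.5	2.5	<5
T	OVT16	Bacillus	positive	2.5	2.5	<0.5	<0.5	10	<5
T	OVT24	Bacillus	positive	2.5	1.25	<0.5	<0.5	2.5	<5
L	OVL12	Bacillus	positive	10	5	<0.5	1	<1	<5
T	OVT5	Bacillus	positive	10	<0.5	<0.5	2.5	2.5	<5
F	OVF21	Bacillus	positive	50	2.5	<0.5	10	2.5	<5
S	OVS24	Bacillus	positive	>50	<0.5	<0.5	5	2.5	<5
T	OVT10	Bacillus	positive	50	<0.5	<0.5	5	2.5	<5
T	OVT20	Bacillus	positive	50	5	<0.5	10	2.5	<5
L	OVL16	Cellulosimicrobium	positive	>50	12.5	50	>50	10	<5
T	OVT9	Chryseobacterium	negative	>50	>25	1	>50	>50	<5
S	OVS2	Curtobacterium	positive	<0.5	2.5	2.5	>50	2.5	<5
S	OVS11	Curtobacterium	positive	<0.5	12.5	50	>50	<1	<5
S	OVS12	Curtobacterium	positive	<0.5	12.5	50	>50	<1	<5
S	OVS13	Curtobacterium	positive	<0.5	2.5	50	50	<1	<5
S	OVS15	Curtobacterium	positive	<0.5	12.5	50	>50	<1	<5
L	OVL10	Curtobacterium	positive	2.5	1.25	<0.5	10	<1	<5
S	OVS27	Lysinibacillus	positive	>50	1.25	2.5	1	2.5	10
L	OVL14	Microbacterium	positive	5	12.5	5	>50	<1	<5
F	OVF19	Micrococcus	positive	10	1.25	5	50	<1	<5
F	OVF24	Micrococcus	positive	>50	1.25	5	50	<1	<5
F	OVF3	Paenibacillus	positive	2.5	<0.5	<0.5	<0.5	2.5	10
F	OVF10	Paenibacillus	positive	2.5	2.5	<0.5	<0.5	<1	<5
F	OVF2	Pantoea	negative	10	2.5	<0.5	10	2.5	10
F	OVF14	Pantoea	negative	10	2.5	<0.5	10	2.5	10
F	OVF1	Pantoea	negative	>50	2.5	<0.5	10	2.5	10
F	OVF9	Pantoea	negative	50	2.5	<0.5	10	2.5	10
F	OVF11	Pantoea	negative	50	2.5	<0.5	5	2.5	10
F	OVF4	Pseudomonas	negative	5	2.5	<0.5	2.5	25	<5
L	OVL17	Pseudomonas	negative	5	2.5	<0.5	1	25	<5
S	OVS9	Pseudomonas	negative	<0.5	2.5	<0.5	2.5	25	10
S	OVS14	Pseudomonas	negative	<0.5	1.25	<0.5	<0.5	25	10
F	OVF7	Pseudomonas	negative	2.5	<0.5	<0.5	<0.5	2.5	<5
F	OVF17	Rathaybacter	positive	2.5	<0.5	2.5	10	<1	<5
F	OVF6	Rhizobium	negative	5	2.5	<0.5	50	2.5	<5
S	OVS20	Rhodococcus	positive	<0.5	2.5	<0.5	10	<1	<5
F	OVF18	Rhodococcus	positive	2.5	2.5	<0.5	5	<1	<5
S	OVS7	Sphingomonas	negative	<0.5	<0.5	1	<0.5	<1	<5
L	OVL6	Sphingomonas	negative	50	<0.5	<0.5	10	2.5	<5
S	OVS22	Staphylococcus	positive	<0.5	1.25	1	>50	2.5	<5
T	OVT21	Staphylococcus	positive	10	<0.5	<0.5	>50	2.5	<5
L	OVL18	Xanthomonas	negative	50	5	<0.5	10	5	<5
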