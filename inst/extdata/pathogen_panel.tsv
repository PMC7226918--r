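target_id	species	group	gram	origin
SA_ATCC25923	Staphylococcus aureus	S_aureus	positive	reference
SA_2668	Staphylococcus aureus	S_aureus	positive	food
SA_2749	Staphylococcus aureus	S_aureus	positive	healthy_subject
SA_3709	Staphylococcus aureus	S_aureus	positive	food
SA_3710	Staphylococcus aureus	S_aureus	positive	food
SA_4070	Staphylococcus aureus	S_aureus	positive	food
SA_4168	Staphylococcus aureus	S_aureus	positive	food
SA_4302	Staphylococcus aureus	S_aureus	positive	food
SA_4691	Staphylococcus aureus	S_aureus	positive	patient
SA_4708	Staphylococcus aureus	S_aureus	positive	patient
SH_5284	Staphylococcus haemolyticus	CoNS	positive	hospital_device
SH_5285	Staphylococcus haemolyticus	CoNS	positive	hospital_device
SH_5383	Staphylococcus haemolyticus	CoNS	positive	hospital_device
SH_5396	Staphylococcus haemolyticus	CoNS	positive	healthy_subject
SE_5318	Staphylococcus epidermidis	CoNS	positive	healthy_subject
SE_5321	Staphylococcus epidermidis	CoNS	positive	healthy_subject
SE_5323	Staphylococcus epidermidis	CoNS	positive	healthy_subject
SE_5377	Staphylococcus epidermidis	CoNS	positive	hospital_device
SE_5403	Staphylococcus epidermidis	CoNS	positive	healthy_subject
SE_5419	Staphylococcus epidermidis	CoNS	positive	food
PA_ATCC27853	Pseudomonas aeruginosa	P_aeruginosa	negative	reference
PA_4177	Pseudomonas aeruginosa	P_aeruginosa	negative	hospital_device
PA_4189	Pseudomonas aeruginosa	P_aeruginosa	negative	hospital_device
PA_5234	Pseudomonas aeruginosa	P_aeruginosa	negative	hospital_device
PA_5245	Pseudomonas aeruginosa	P_aeruginosa	negative	hospital_device
PA_5246	Pseudomonas aeruginosa	P_aeruginosa	negative	hospital_device
PA_5255	Pseudomonas aeruginosa	P_aeruginosa	negative	hospital_device
PA_5139	Pseudomonas aeruginosa	P_aeruginosa	negative	hospital_device
PA_5009	Pseudomonas aeruginosa	P_aeruginosa	negative	hospital_device
PA_5236	Pseudomonas aeruginosa	P_aeruginosa	negative	hospital_device
KP_ATCC700603	Klebsiella pneumoniae	K_pneumoniae	negative	reference
KP_4409	Klebsiella pneumoniae	K_pneumoniae	negative	patient
KP_4412	Klebsiella pneumoniae	K_pneumoniae	negative	patient
KP_4417	Klebsiella pneumoniae	K_pneumoniae	negative	patient
KP_4420	Klebsiella pneumoniae	K_pneumoniae	negative	patient
KP_4422	Klebsiella pneumoniae	K_pneumoniae	negative	patient
BC_FCF3	Burkholderia cepacia	BCC	negative	cystic_fibrosis
BC_FCF23	Burkholderia cenocepacia	BCC	negative	cystic_fibrosis
BC_LMG13010	Burkholderia multivorans	BCC	negative	cystic_fibrosis
BC_LMG16656	Burkholderia ambifaria	BCC	negative	cystic_fibrosis
BC_LMG21462	Burkholderia cenocepacia	BCC	negative	cystic_fibrosis
BC_LMG24506	Burkholderia cenocepacia	BCC	negative	cystic_fibrosis
BC_LMG1222	Burkholderia cepacia	BCC	negative	environment
BC_LMG17588	Burkholderia multivorans	BCC	negative	environment
BC_LMG19182	Burkholderia ambifaria	BCC	negative	environment
BC_LMG19230	Burkholderia cenocepacia	BCC	negative	environment
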