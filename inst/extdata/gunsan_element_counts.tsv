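element	age_class	left	right	unsided
Frontal	adult	0	0	6
Frontal	subadult	0	0	2
Parietal	adult	6	6	0
Parietal	subadult	1	2	0
Temporal	adult	6	6	0
Temporal	subadult	2	2	0
Occipital	adult	0	0	6
Occipital	subadult	0	0	1
Maxilla	adult	3	5	0
Maxilla	subadult	1	1	0
Mandible	adult	5	4	0
Mandible	subadult	1	2	0
Clavicle	adult	4	5	0
Clavicle	subadult	0	0	0
Scapula	adult	5	5	0
Scapula	subadult	0	0	0
Humerus	adult	5	5	0
Humerus	subadult	2	3	0
Radius	adult	4	5	0
Radius	subadult	1	2	0
Ulna	adult	5	5	0
Ulna	subadult	2	3	0
Os_coxae	adult	5	6	0
Os_coxae	subadult	0	2	0
Femur	adult	5	5	0
Femur	subadult	3	3	0
Tibia	adult	5	5	0
Tibia	subadult	3	2	0
Fibula	adult	5	5	0
Fibula	subadult	0	0	0
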