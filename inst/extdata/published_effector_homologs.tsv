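query_id	source_species	subject_protein_id	percent_identity	deg_status
C002	Acyrthosiphon pisum	XP_027848216.1	55	n.s.
Armet	Acyrthosiphon pisum	XP_027850649.1	95	n.s.
Me10	Macrosiphum euphorbiae	XP_027842596.1	55	n.s.
Me23	Macrosiphum euphorbiae	XP_027842036.1	55	n.s.
Me47	Macrosiphum euphorbiae	XP_027847499.1	54	n.s.
AcDCXR	Aphis craccivora	XP_027848224.1	99	n.s.
Mp1	Myzus persicae	XP_027842597.1	51	n.s.
Mp10	Myzus persicae	XP_027847843.1	93	n.s.
Mp55	Myzus persicae	XP_027849472.1	46	n.s.
Mp56	Myzus persicae	XP_027850553.1	89	n.s.
Mp57	Myzus persicae	XP_027846130.1	32	n.s.
Mp58	Myzus persicae	XP_027842596.1	69	n.s.
ACE1	Acyrthosiphon pisum	XP_027838689.1	86	n.s.
ACE2	Acyrthosiphon pisum	XP_027838669.1	95	n.s.
ACE3	Acyrthosiphon pisum	XP_027850009.1	96	n.s.
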