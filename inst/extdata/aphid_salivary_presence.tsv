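protein	Sa	Ap	Mp	Mc	Rp	Sg	Me	Sc	Ac	Dn
Actin	1	1	1	1	1	0	1	1	1	0
Glucose dehydrogenase	1	1	1	1	1	1	1	0	1	1
Peroxidase	1	1	1	1	1	0	1	0	0	0
Heat shock protein	1	0	1	0	0	0	1	0	1	0
Carboxypeptidase	0	0	0	0	1	0	0	0	0	0
14-3-3 protein	0	0	1	0	0	0	1	0	0	0
EF1-alpha	1	1	1	0	0	0	0	0	1	0
40S ribosomal protein	1	0	0	0	0	0	0	0	0	0
60S ribosomal protein	1	0	0	0	0	0	0	0	0	0
Endochitinase	0	0	0	0	0	0	0	0	1	0
Calreticulin	0	0	0	0	0	0	0	0	0	1
Histone	1	1	1	0	0	0	1	1	1	0
Carbonic anhydrase	1	0	1	1	1	1	1	0	1	0
Apolipophorins	1	1	1	0	1	0	1	0	0	0
ATP synthase	1	0	1	0	0	0	1	0	1	0
Tubulin	1	0	1	0	0	0	0	1	1	0
ASC1	1	0	0	0	0	0	0	0	0	0
MINPP	0	0	0	0	1	0	0	0	0	0
RNA-binding protein	0	0	0	0	0	1	0	0	0	0
LOC114119699	1	0	0	0	0	0	1	0	0	0
LOC114120354	1	1	1	0	1	0	1	0	0	0
LOC114128856	1	0	0	0	0	0	1	0	0	0
LOC114129844	0	0	0	0	0	1	1	0	0	0
LOC114124500	1	0	1	1	1	0	1	0	0	0
PF11_0213-like	0	0	0	0	0	0	1	0	0	0
LOC114124821	0	0	0	0	0	0	1	0	0	0
LOC114118907	0	1	1	1	1	0	0	0	0	0
LOC114119100	0	0	0	0	1	0	0	0	0	0
LOC114119139	0	0	0	0	0	0	1	0	0	0
LOC114124575	1	1	1	0	0	0	1	0	0	0
LOC114133079	1	1	1	1	1	1	1	0	1	1
LOC114123730	1	1	1	0	1	0	1	0	0	0
LOC114123729	1	1	1	0	0	0	1	0	0	0
LOC114128009	1	1	1	0	0	0	1	0	1	0
LOC114123311	0	0	0	0	1	0	1	0	0	0
LOC114121223	0	1	0	0	0	0	1	0	0	0
LOC114130459	1	1	0	0	0	0	1	0	0	0
DDB_G0267840	0	0	0	0	1	0	0	0	0	0
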