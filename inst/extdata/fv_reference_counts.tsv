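isolate	accession	n_cassettes	n_box_cassettes
BFV_Riems	JX307862.1	1	0
BFV_100	JX307861.1	1	0
BFV_11	U94514.1	1	0
BFV_3026	AY134750.1	1	0
EFV	AF201902.1	1	0
FFV_Chatul-3	AJ564746.1	4	4
FFV_F17	U85043.1	4	4
FFV_FUV	NC_039242.1	4	4
FFV_Pco	KC292054.1	3	3
HFV	U21247.1	1	0
HSRV1	Y07723.1	1	0
HSRV2	Y07724.1	1	0
PFV	Y07725.1	1	0
SFV_AG15	JQ867462.1	1	0
SFV_agm	NC_010820.1	2	1
SFV_AXX	EU010385.1	5	3
SFV_BAD327	JQ867463.1	1	0
SFV_BAD468	JQ867465.1	1	0
SFV_BAK74	JQ867464.1	0	0
SFV_CAE_FV2014	MF582544.1	2	1
SFV_CAE_LK3	M74895.1	2	1
SFV_CJA	GU356395.1	1	0
SFV_CNI	JQ867466.1	3	1
SFV_CPZ	U04327.1	1	0
SFV_GOR	HM245790.1	1	0
SFV_MAC	X54482.1	1	0
SFV_MCY	KF026286.1	1	0
SFV_MFA	LC094267.1	1	0
SFV_MFU	AB923518.1	1	0
SFV_MMU	MF280817.1	1	0
SFV_OCR	KM233624.1	1	0
SFV_ORA	NC_039085.1	2	1
SFV_PPY	AJ544579.1	3	2
SFV_PSC	KX087159	1	0
SFV_PVE	NC_001364.1	1	0
SFV_SSC	GU356394.1	1	0
SFV_SXA	KP143760.1	1	0
SFV-6	L25422	1	1
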