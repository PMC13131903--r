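abbreviation	full_name
CA	Anterior Commissure
CC_1	Corpus Callosum: Rostrum
CC_2	Corpus Callosum: Genu
CC_3	Corpus Callosum: Rostral Midbody
CC_4	Corpus Callosum: Anterior Midbody
CC_5	Corpus Callosum: Posterior Midbody
CC_6	Corpus Callosum: Isthmus
CC_7	Corpus Callosum: Splenium
MCP	Middle Cerebellar Peduncle
AF_left	Left Arcuate Fasciculus
AF_right	Right Arcuate Fasciculus
ATR_left	Left Anterior Thalamic Radiation
ATR_right	Right Anterior Thalamic Radiation
CG_left	Left Cingulum
CG_right	Right Cingulum
CST_left	Left Corticospinal Tract
CST_right	Right Corticospinal Tract
FX_left	Left Fornix
FX_right	Right Fornix
ICP_left	Left Inferior Cerebellar Peduncle
ICP_right	Right Inferior Cerebellar Peduncle
IFO_left	Left Inferior Fronto-Occipital Fasciculus
IFO_right	Right Inferior Fronto-Occipital Fasciculus
ILF_left	Left Inferior Longitudinal Fasciculus
ILF_right	Right Inferior Longitudinal Fasciculus
MLF_left	Left Middle Longitudinal Fasciculus
MLF_right	Right Middle Longitudinal Fasciculus
OR_left	Left Optic Radiation
OR_right	Right Optic Radiation
SCP_left	Left Superior Cerebellar Peduncle
SCP_right	Right Superior Cerebellar Peduncle
SLF_I_left	Left Superior Longitudinal Fasciculus I
SLF_I_right	Right Superior Longitudinal Fasciculus I
SLF_II_left	Left Superior Longitudinal Fasciculus II
SLF_II_right	Right Superior Longitudinal Fasciculus II
SLF_III_left	Left Superior Longitudinal Fasciculus III
SLF_III_right	Right Superior Longitudinal Fasciculus III
ST_OCC_left	Left Striato-Occipital Tract
ST_OCC_right	Right Striato-Occipital Tract
ST_PAR_left	Left Striato-Parietal Tract
ST_PAR_right	Right Striato-Parietal Tract
STR_left	Left Superior Thalamic Radiation
STR_right	Right Superior Thalamic Radiation
T_OCC_left	Left Thalamo-Occipital Tract
T_OCC_right	Right Thalamo-Occipital Tract
T_PAR_left	Left Thalamo-Parietal Tract
T_PAR_right	Right Thalamo-Parietal Tract
UF_left	Left Uncinate Fasciculus
UF_right	Right Uncinate Fasciculus
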