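id	class
CDH1	Epi
DSP	Epi
KRT8	Epi
KRT18	Epi
EPCAM	Epi
VIM	Mes
FN1	Mes
CDH2	Mes
ZEB1	Mes
SNAI2	Mes
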