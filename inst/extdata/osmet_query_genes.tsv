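gene	on_array
BIRC5	yes
CAV1	yes
CCN1	yes
CCN3	yes
CD44	yes
CDH11	yes
CDH2	yes
COL18A1	yes
CXCR4	yes
DPF2	yes
EGFR	yes
EZR	yes
FAS	yes
IGF1	yes
IGF2	yes
IGF1R	yes
IVD	yes
KIT	yes
LRP5	yes
MMP2	yes
PDGFRA	yes
PEDF	yes
PLAUR	yes
RECK	yes
S100A6	yes
SPARC	yes
TIMP1	yes
VEGFA	yes
VEGFB	yes
VEGFC	yes
WIF1	yes
YYI	yes
CXCR3	no
EGF	no
EGFR2	no
FADD	no
HIF1	no
IL12A	no
IL12B	no
INS	no
MAML1	no
MIRK	no
MMP14	no
MMP9	no
PDGFA	no
VCP	no
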