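gene	cell_type
RBFOX3	neuron
SNAP25	neuron
SYT1	neuron
SLC17A7	neuron
GABRA1	neuron
NEFL	neuron
GRIN1	neuron
STMN2	neuron
SYN1	neuron
ENO2	neuron
GFAP	astrocyte
AQP4	astrocyte
SLC1A2	astrocyte
SLC1A3	astrocyte
ALDH1L1	astrocyte
GJA1	astrocyte
S100B	astrocyte
SOX9	astrocyte
MBP	oligodendrocyte
MOG	oligodendrocyte
MOBP	oligodendrocyte
PLP1	oligodendrocyte
MAG	oligodendrocyte
CNP	oligodendrocyte
SOX10	oligodendrocyte
OLIG2	oligodendrocyte
AIF1	microglia
CX3CR1	microglia
P2RY12	microglia
TMEM119	microglia
C1QA	microglia
CSF1R	microglia
ITGAM	microglia
TYROBP	microglia
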