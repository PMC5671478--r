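# RT-qPCR primer assay metrics for the 21-assay poplar candidate panel:
# LinRegPCR amplification efficiency and calibration-curve R-squared.
gene	efficiency	r2
SSU_S4e	1.931	0.999
SSU_S8e	1.902	0.998
DnaJ_A2	1.825	0.996
CDPK	1.928	0.997
26S_PRS	1.945	0.998
UbqCE	1.615	0.993
LSU_L5e	1.874	0.999
20S_PSU	1.945	0.996
TIF5A_uni	1.605	0.995
TIF5A_iso	1.860	0.996
ACT_iso	1.856	0.997
ACT_uni	1.926	0.996
EF1b	1.885	0.997
UBQ10-9	1.919	0.998
UBQ10-5	1.923	0.997
18S_RNA	1.973	0.999
CDC2	1.919	0.996
HIS	1.897	0.999
CYP	1.923	0.996
IF5A	1.913	0.997
RA	1.926	0.999
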