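# Reporter-construct truth table (feature-vector encoding).
# 16 rows: AAT 1-33; synTP 3R/2R/0R/3K; eight 1R scan constructs
#   (the R13 row doubles as the arginine series' 1R member);
#   FMNL 1-24 wt; FMNL E2A (E18A folded: identical features/outcome);
#   FMNL E2A/E18A (RPSA 1-24 folded: identical signature/outcome).
# basic_positions for AAT / multi-R rows are representative non-flank
#   stand-ins (synthetic); the classifier consumes only the counts.
label	window	basic_positions	n_acidic	observed
AAT_1-33	33	5,12	0	mitochondrion
synTP_3R	24	6,9,13	0	mitochondrion
synTP_2R	24	9,13	0	mitochondrion
synTP_0R	24		0	cytosol
synTP_3K	24	6,9,13	0	mitochondrion
synTP_1R_R2	24	2	0	cytosol
synTP_1R_R6	24	6	0	mitochondrion
synTP_1R_R8	24	8	0	mitochondrion
synTP_1R_R9	24	9	0	mitochondrion
synTP_1R_R12	24	12	0	mitochondrion
synTP_1R_R13	24	13	0	mitochondrion
synTP_1R_R15	24	15	0	mitochondrion
synTP_1R_R21	24	21	0	mitochondrion
FMNL_1-24	24	9	2	cytosol
FMNL_E2A	24	9	1	cytosol
FMNL_E2A/E18A	24	9	0	mitochondrion
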