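symbol	direction	source
ACSL4	positive	reconstructed:driver_review
LPCAT3	positive	reconstructed:driver_review
ALOX5	positive	reconstructed:driver_review
ALOX12	positive	reconstructed:driver_review
ALOX15	positive	reconstructed:driver_review
ALOX15B	positive	reconstructed:driver_review
ALOXE3	positive	reconstructed:driver_review
TP53	positive	reconstructed:driver_review
TFRC	positive	reconstructed:driver_review
NCOA4	positive	reconstructed:driver_review
HMOX1	positive	reconstructed:driver_review
STEAP3	positive	reconstructed:driver_review
SLC1A5	positive	reconstructed:driver_review
GLS2	positive	reconstructed:driver_review
CS	positive	reconstructed:driver_review
ACSF2	positive	reconstructed:driver_review
ATG5	positive	reconstructed:driver_review
ATG7	positive	reconstructed:driver_review
NOX1	positive	reconstructed:driver_review
CYBB	positive	reconstructed:driver_review
NOX4	positive	reconstructed:driver_review
PEBP1	positive	reconstructed:driver_review
ZEB1	positive	reconstructed:driver_review
CARS1	positive	reconstructed:driver_review
CHAC1	positive	reconstructed:driver_review
EMC2	positive	reconstructed:driver_review
VDAC2	positive	reconstructed:driver_review
VDAC3	positive	reconstructed:driver_review
KEAP1	positive	reconstructed:driver_review
DPP4	positive	reconstructed:driver_review
BAP1	positive	reconstructed:driver_review
BECN1	positive	reconstructed:driver_review
IREB2	positive	reconstructed:driver_review
SAT1	positive	reconstructed:driver_review
BID	positive	reconstructed:driver_review
GPX4	negative	reconstructed:suppressor_review
SLC7A11	negative	reconstructed:suppressor_review
SLC3A2	negative	reconstructed:suppressor_review
NFE2L2	negative	reconstructed:suppressor_review
NQO1	negative	reconstructed:suppressor_review
CD44	negative	reconstructed:suppressor_review
AKR1C1	negative	reconstructed:suppressor_review
AKR1C2	negative	reconstructed:suppressor_review
AKR1C3	negative	reconstructed:suppressor_review
FTH1	negative	reconstructed:suppressor_review
FTL	negative	reconstructed:suppressor_review
HSPA5	negative	reconstructed:suppressor_review
HSPB1	negative	reconstructed:suppressor_review
NFS1	negative	reconstructed:suppressor_review
FANCD2	negative	reconstructed:suppressor_review
GCLC	negative	reconstructed:suppressor_review
GCLM	negative	reconstructed:suppressor_review
GSS	negative	reconstructed:suppressor_review
CBS	negative	reconstructed:suppressor_review
CISD1	negative	reconstructed:suppressor_review
CISD2	negative	reconstructed:suppressor_review
AIFM2	negative	reconstructed:suppressor_review
PRDX6	negative	reconstructed:suppressor_review
SCD	negative	reconstructed:suppressor_review
SQLE	negative	reconstructed:suppressor_review
CAV1	negative	reconstructed:suppressor_review
ACSL3	negative	reconstructed:suppressor_review
SLC40A1	negative	reconstructed:suppressor_review
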