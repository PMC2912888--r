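resid	elety	class
ALA	C	C_BB
ALA	CA	CA_BB
ALA	CB	C_ALI_CH3
ALA	N	N_BB
ALA	O	O_BB
ARG	C	C_BB
ARG	CA	CA_BB
ARG	CB	C_ALI_CH2
ARG	CD	C_ALI_CH2
ARG	CG	C_ALI_CH2
ARG	CZ	C_GUANIDO
ARG	N	N_BB
ARG	NE	N_GUANIDINIUM
ARG	NH1	N_GUANIDINIUM
ARG	NH2	N_GUANIDINIUM
ARG	O	O_BB
ASN	C	C_BB
ASN	CA	CA_BB
ASN	CB	C_ALI_CH2
ASN	CG	C_AMIDE
ASN	N	N_BB
ASN	ND2	N_AMIDE
ASN	O	O_BB
ASN	OD1	O_AMIDE
ASP	C	C_BB
ASP	CA	CA_BB
ASP	CB	C_ALI_CH2
ASP	CG	C_CARBOXYL
ASP	N	N_BB
ASP	O	O_BB
ASP	OD1	O_CARBOXYL
ASP	OD2	O_CARBOXYL
CYS	C	C_BB
CYS	CA	CA_BB
CYS	CB	C_ALI_CH2
CYS	N	N_BB
CYS	O	O_BB
CYS	SG	S_THIOL
GLN	C	C_BB
GLN	CA	CA_BB
GLN	CB	C_ALI_CH2
GLN	CD	C_AMIDE
GLN	CG	C_ALI_CH2
GLN	N	N_BB
GLN	NE2	N_AMIDE
GLN	O	O_BB
GLN	OE1	O_AMIDE
GLU	C	C_BB
GLU	CA	CA_BB
GLU	CB	C_ALI_CH2
GLU	CD	C_CARBOXYL
GLU	CG	C_ALI_CH2
GLU	N	N_BB
GLU	O	O_BB
GLU	OE1	O_CARBOXYL
GLU	OE2	O_CARBOXYL
GLY	C	C_BB
GLY	CA	CA_BB
GLY	N	N_BB
GLY	O	O_BB
HIS	C	C_BB
HIS	CA	CA_BB
HIS	CB	C_ALI_CH2
HIS	CD2	C_ARO
HIS	CE1	C_ARO
HIS	CG	C_ARO
HIS	N	N_BB
HIS	ND1	N_RING
HIS	NE2	N_RING
HIS	O	O_BB
ILE	C	C_BB
ILE	CA	CA_BB
ILE	CB	C_ALI_CH1
ILE	CD1	C_ALI_CH3
ILE	CG1	C_ALI_CH2
ILE	CG2	C_ALI_CH3
ILE	N	N_BB
ILE	O	O_BB
LEU	C	C_BB
LEU	CA	CA_BB
LEU	CB	C_ALI_CH2
LEU	CD1	C_ALI_CH3
LEU	CD2	C_ALI_CH3
LEU	CG	C_ALI_CH1
LEU	N	N_BB
LEU	O	O_BB
LYS	C	C_BB
LYS	CA	CA_BB
LYS	CB	C_ALI_CH2
LYS	CD	C_ALI_CH2
LYS	CE	C_ALI_CH2
LYS	CG	C_ALI_CH2
LYS	N	N_BB
LYS	NZ	N_AMINE
LYS	O	O_BB
MET	C	C_BB
MET	CA	CA_BB
MET	CB	C_ALI_CH2
MET	CE	C_ALI_CH3
MET	CG	C_ALI_CH2
MET	N	N_BB
MET	O	O_BB
MET	SD	S_THIOETHER
PHE	C	C_BB
PHE	CA	CA_BB
PHE	CB	C_ALI_CH2
PHE	CD1	C_ARO
PHE	CD2	C_ARO
PHE	CE1	C_ARO
PHE	CE2	C_ARO
PHE	CG	C_ARO
PHE	CZ	C_ARO
PHE	N	N_BB
PHE	O	O_BB
PRO	C	C_BB
PRO	CA	CA_BB
PRO	CB	C_ALI_CH2
PRO	CD	C_ALI_CH2
PRO	CG	C_ALI_CH2
PRO	N	N_BB
PRO	O	O_BB
SER	C	C_BB
SER	CA	CA_BB
SER	CB	C_ALI_CH2
SER	N	N_BB
SER	O	O_BB
SER	OG	O_HYDROXYL
THR	C	C_BB
THR	CA	CA_BB
THR	CB	C_ALI_CH1
THR	CG2	C_ALI_CH3
THR	N	N_BB
THR	O	O_BB
THR	OG1	O_HYDROXYL
TRP	C	C_BB
TRP	CA	CA_BB
TRP	CB	C_ALI_CH2
TRP	CD1	C_ARO
TRP	CD2	C_ARO
TRP	CE2	C_ARO
TRP	CE3	C_ARO
TRP	CG	C_ARO
TRP	CH2	C_ARO
TRP	CZ2	C_ARO
TRP	CZ3	C_ARO
TRP	N	N_BB
TRP	NE1	N_RING
TRP	O	O_BB
TYR	C	C_BB
TYR	CA	CA_BB
TYR	CB	C_ALI_CH2
TYR	CD1	C_ARO
TYR	CD2	C_ARO
TYR	CE1	C_ARO
TYR	CE2	C_ARO
TYR	CG	C_ARO
TYR	CZ	C_ARO
TYR	N	N_BB
TYR	O	O_BB
TYR	OH	O_HYDROXYL
VAL	C	C_BB
VAL	CA	CA_BB
VAL	CB	C_ALI_CH1
VAL	CG1	C_ALI_CH3
VAL	CG2	C_ALI_CH3
VAL	N	N_BB
VAL	O	O_BB
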