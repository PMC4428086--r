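residue	atom	charge	sigma	eps	radius
ALA	N	-0.2	3.25	0.17	1.7
ALA	CA	0.2	3.6	0.12	1.9
ALA	C	0.45	3.6	0.12	1.9
ALA	O	-0.45	2.96	0.21	1.5
ALA	CB	0	3.6	0.12	1.9
GLY	N	-0.2	3.25	0.17	1.7
GLY	CA	0.2	3.6	0.12	1.9
GLY	C	0.45	3.6	0.12	1.9
GLY	O	-0.45	2.96	0.21	1.5
VAL	N	-0.2	3.25	0.17	1.7
VAL	CA	0.2	3.6	0.12	1.9
VAL	C	0.45	3.6	0.12	1.9
VAL	O	-0.45	2.96	0.21	1.5
VAL	CB	0	3.6	0.12	1.9
VAL	CG1	0	3.6	0.12	1.9
VAL	CG2	0	3.6	0.12	1.9
LEU	N	-0.2	3.25	0.17	1.7
LEU	CA	0.2	3.6	0.12	1.9
LEU	C	0.45	3.6	0.12	1.9
LEU	O	-0.45	2.96	0.21	1.5
LEU	CB	0	3.6	0.12	1.9
LEU	CG	0	3.6	0.12	1.9
LEU	CD1	0	3.6	0.12	1.9
LEU	CD2	0	3.6	0.12	1.9
ILE	N	-0.2	3.25	0.17	1.7
ILE	CA	0.2	3.6	0.12	1.9
ILE	C	0.45	3.6	0.12	1.9
ILE	O	-0.45	2.96	0.21	1.5
ILE	CB	0	3.6	0.12	1.9
ILE	CG1	0	3.6	0.12	1.9
ILE	CG2	0	3.6	0.12	1.9
ILE	CD1	0	3.6	0.12	1.9
PRO	N	-0.2	3.25	0.17	1.7
PRO	CA	0.2	3.6	0.12	1.9
PRO	C	0.45	3.6	0.12	1.9
PRO	O	-0.45	2.96	0.21	1.5
PRO	CB	0	3.6	0.12	1.9
PRO	CG	0	3.6	0.12	1.9
PRO	CD	0	3.6	0.12	1.9
PHE	N	-0.2	3.25	0.17	1.7
PHE	CA	0.2	3.6	0.12	1.9
PHE	C	0.45	3.6	0.12	1.9
PHE	O	-0.45	2.96	0.21	1.5
PHE	CB	0	3.6	0.12	1.9
PHE	CG	0	3.6	0.12	1.9
PHE	CD1	0	3.6	0.12	1.9
PHE	CD2	0	3.6	0.12	1.9
PHE	CE1	0	3.6	0.12	1.9
PHE	CE2	0	3.6	0.12	1.9
PHE	CZ	0	3.6	0.12	1.9
TRP	N	-0.2	3.25	0.17	1.7
TRP	CA	0.2	3.6	0.12	1.9
TRP	C	0.45	3.6	0.12	1.9
TRP	O	-0.45	2.96	0.21	1.5
TRP	CB	0	3.6	0.12	1.9
TRP	CG	0	3.6	0.12	1.9
TRP	CD1	0	3.6	0.12	1.9
TRP	CD2	0	3.6	0.12	1.9
TRP	NE1	0	3.25	0.17	1.7
TRP	CE2	0	3.6	0.12	1.9
TRP	CE3	0	3.6	0.12	1.9
TRP	CZ2	0	3.6	0.12	1.9
TRP	CZ3	0	3.6	0.12	1.9
TRP	CH2	0	3.6	0.12	1.9
MET	N	-0.2	3.25	0.17	1.7
MET	CA	0.2	3.6	0.12	1.9
MET	C	0.45	3.6	0.12	1.9
MET	O	-0.45	2.96	0.21	1.5
MET	CB	0	3.6	0.12	1.9
MET	CG	0	3.6	0.12	1.9
MET	SD	0	3.55	0.25	1.8
MET	CE	0	3.6	0.12	1.9
SER	N	-0.2	3.25	0.17	1.7
SER	CA	0.2	3.6	0.12	1.9
SER	C	0.45	3.6	0.12	1.9
SER	O	-0.45	2.96	0.21	1.5
SER	CB	0.4	3.6	0.12	1.9
SER	OG	-0.4	2.96	0.21	1.5
THR	N	-0.2	3.25	0.17	1.7
THR	CA	0.2	3.6	0.12	1.9
THR	C	0.45	3.6	0.12	1.9
THR	O	-0.45	2.96	0.21	1.5
THR	CB	0.4	3.6	0.12	1.9
THR	OG1	-0.4	2.96	0.21	1.5
THR	CG2	0	3.6	0.12	1.9
CYS	N	-0.2	3.25	0.17	1.7
CYS	CA	0.2	3.6	0.12	1.9
CYS	C	0.45	3.6	0.12	1.9
CYS	O	-0.45	2.96	0.21	1.5
CYS	CB	0.2	3.6	0.12	1.9
CYS	SG	-0.2	3.55	0.25	1.8
TYR	N	-0.2	3.25	0.17	1.7
TYR	CA	0.2	3.6	0.12	1.9
TYR	C	0.45	3.6	0.12	1.9
TYR	O	-0.45	2.96	0.21	1.5
TYR	CB	0	3.6	0.12	1.9
TYR	CG	0	3.6	0.12	1.9
TYR	CD1	0	3.6	0.12	1.9
TYR	CD2	0	3.6	0.12	1.9
TYR	CE1	0	3.6	0.12	1.9
TYR	CE2	0	3.6	0.12	1.9
TYR	CZ	0.4	3.6	0.12	1.9
TYR	OH	-0.4	2.96	0.21	1.5
ASN	N	-0.2	3.25	0.17	1.7
ASN	CA	0.2	3.6	0.12	1.9
ASN	C	0.45	3.6	0.12	1.9
ASN	O	-0.45	2.96	0.21	1.5
ASN	CB	0	3.6	0.12	1.9
ASN	CG	0.45	3.6	0.12	1.9
ASN	OD1	-0.45	2.96	0.21	1.5
ASN	ND2	0	3.25	0.17	1.7
GLN	N	-0.2	3.25	0.17	1.7
GLN	CA	0.2	3.6	0.12	1.9
GLN	C	0.45	3.6	0.12	1.9
GLN	O	-0.45	2.96	0.21	1.5
GLN	CB	0	3.6	0.12	1.9
GLN	CG	0	3.6	0.12	1.9
GLN	CD	0.45	3.6	0.12	1.9
GLN	OE1	-0.45	2.96	0.21	1.5
GLN	NE2	0	3.25	0.17	1.7
ASP	N	-0.2	3.25	0.17	1.7
ASP	CA	0.2	3.6	0.12	1.9
ASP	C	0.45	3.6	0.12	1.9
ASP	O	-0.45	2.96	0.21	1.5
ASP	CB	0	3.6	0.12	1.9
ASP	CG	0.27	3.6	0.12	1.9
ASP	OD1	-0.635	2.96	0.21	1.5
ASP	OD2	-0.635	2.96	0.21	1.5
GLU	N	-0.2	3.25	0.17	1.7
GLU	CA	0.2	3.6	0.12	1.9
GLU	C	0.45	3.6	0.12	1.9
GLU	O	-0.45	2.96	0.21	1.5
GLU	CB	0	3.6	0.12	1.9
GLU	CG	0	3.6	0.12	1.9
GLU	CD	0.27	3.6	0.12	1.9
GLU	OE1	-0.635	2.96	0.21	1.5
GLU	OE2	-0.635	2.96	0.21	1.5
LYS	N	-0.2	3.25	0.17	1.7
LYS	CA	0.2	3.6	0.12	1.9
LYS	C	0.45	3.6	0.12	1.9
LYS	O	-0.45	2.96	0.21	1.5
LYS	CB	0	3.6	0.12	1.9
LYS	CG	0	3.6	0.12	1.9
LYS	CD	0	3.6	0.12	1.9
LYS	CE	0	3.6	0.12	1.9
LYS	NZ	1	3.25	0.17	1.7
ARG	N	-0.2	3.25	0.17	1.7
ARG	CA	0.2	3.6	0.12	1.9
ARG	C	0.45	3.6	0.12	1.9
ARG	O	-0.45	2.96	0.21	1.5
ARG	CB	0	3.6	0.12	1.9
ARG	CG	0	3.6	0.12	1.9
ARG	CD	0	3.6	0.12	1.9
ARG	NE	0	3.25	0.17	1.7
ARG	CZ	0.34	3.6	0.12	1.9
ARG	NH1	0.33	3.25	0.17	1.7
ARG	NH2	0.33	3.25	0.17	1.7
HIS	N	-0.2	3.25	0.17	1.7
HIS	CA	0.2	3.6	0.12	1.9
HIS	C	0.45	3.6	0.12	1.9
HIS	O	-0.45	2.96	0.21	1.5
HIS	CB	0	3.6	0.12	1.9
HIS	CG	0	3.6	0.12	1.9
HIS	ND1	-0.2	3.25	0.17	1.7
HIS	CD2	0	3.6	0.12	1.9
HIS	CE1	0.4	3.6	0.12	1.9
HIS	NE2	-0.2	3.25	0.17	1.7
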