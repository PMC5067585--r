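res_name	role	atom	partner_hydrogens
ALA	donor	N	H|H1|H2|H3|HN
ALA	acceptor	O	
ALA	acceptor	OXT	
ARG	donor	N	H|H1|H2|H3|HN
ARG	acceptor	O	
ARG	acceptor	OXT	
ASN	donor	N	H|H1|H2|H3|HN
ASN	acceptor	O	
ASN	acceptor	OXT	
ASP	donor	N	H|H1|H2|H3|HN
ASP	acceptor	O	
ASP	acceptor	OXT	
CYS	donor	N	H|H1|H2|H3|HN
CYS	acceptor	O	
CYS	acceptor	OXT	
GLN	donor	N	H|H1|H2|H3|HN
GLN	acceptor	O	
GLN	acceptor	OXT	
GLU	donor	N	H|H1|H2|H3|HN
GLU	acceptor	O	
GLU	acceptor	OXT	
GLY	donor	N	H|H1|H2|H3|HN
GLY	acceptor	O	
GLY	acceptor	OXT	
HIS	donor	N	H|H1|H2|H3|HN
HIS	acceptor	O	
HIS	acceptor	OXT	
ILE	donor	N	H|H1|H2|H3|HN
ILE	acceptor	O	
ILE	acceptor	OXT	
LEU	donor	N	H|H1|H2|H3|HN
LEU	acceptor	O	
LEU	acceptor	OXT	
LYS	donor	N	H|H1|H2|H3|HN
LYS	acceptor	O	
LYS	acceptor	OXT	
MET	donor	N	H|H1|H2|H3|HN
MET	acceptor	O	
MET	acceptor	OXT	
PHE	donor	N	H|H1|H2|H3|HN
PHE	acceptor	O	
PHE	acceptor	OXT	
PRO	acceptor	O	
PRO	acceptor	OXT	
SER	donor	N	H|H1|H2|H3|HN
SER	acceptor	O	
SER	acceptor	OXT	
THR	donor	N	H|H1|H2|H3|HN
THR	acceptor	O	
THR	acceptor	OXT	
TRP	donor	N	H|H1|H2|H3|HN
TRP	acceptor	O	
TRP	acceptor	OXT	
TYR	donor	N	H|H1|H2|H3|HN
TYR	acceptor	O	
TYR	acceptor	OXT	
VAL	donor	N	H|H1|H2|H3|HN
VAL	acceptor	O	
VAL	acceptor	OXT	
PTR	donor	N	H|H1|H2|H3|HN
PTR	acceptor	O	
PTR	acceptor	OXT	
ALA	sidechain	CB	
ARG	sidechain	CB	
ARG	sidechain	CG	
ARG	sidechain	CD	
ARG	sidechain	NE	
ARG	sidechain	CZ	
ARG	sidechain	NH1	
ARG	sidechain	NH2	
ASN	sidechain	CB	
ASN	sidechain	CG	
ASN	sidechain	OD1	
ASN	sidechain	ND2	
ASP	sidechain	CB	
ASP	sidechain	CG	
ASP	sidechain	OD1	
ASP	sidechain	OD2	
CYS	sidechain	CB	
CYS	sidechain	SG	
GLN	sidechain	CB	
GLN	sidechain	CG	
GLN	sidechain	CD	
GLN	sidechain	OE1	
GLN	sidechain	NE2	
GLU	sidechain	CB	
GLU	sidechain	CG	
GLU	sidechain	CD	
GLU	sidechain	OE1	
GLU	sidechain	OE2	
HIS	sidechain	CB	
HIS	sidechain	CG	
HIS	sidechain	ND1	
HIS	sidechain	CD2	
HIS	sidechain	CE1	
HIS	sidechain	NE2	
ILE	sidechain	CB	
ILE	sidechain	CG1	
ILE	sidechain	CG2	
ILE	sidechain	CD1	
LEU	sidechain	CB	
LEU	sidechain	CG	
LEU	sidechain	CD1	
LEU	sidechain	CD2	
LYS	sidechain	CB	
LYS	sidechain	CG	
LYS	sidechain	CD	
LYS	sidechain	CE	
LYS	sidechain	NZ	
MET	sidechain	CB	
MET	sidechain	CG	
MET	sidechain	SD	
MET	sidechain	CE	
PHE	sidechain	CB	
PHE	sidechain	CG	
PHE	sidechain	CD1	
PHE	sidechain	CD2	
PHE	sidechain	CE1	
PHE	sidechain	CE2	
PHE	sidechain	CZ	
PRO	sidechain	CB	
PRO	sidechain	CG	
PRO	sidechain	CD	
SER	sidechain	CB	
SER	sidechain	OG	
THR	sidechain	CB	
THR	sidechain	OG1	
THR	sidechain	CG2	
TRP	sidechain	CB	
TRP	sidechain	CG	
TRP	sidechain	CD1	
TRP	sidechain	CD2	
TRP	sidechain	NE1	
TRP	sidechain	CE2	
TRP	sidechain	CE3	
TRP	sidechain	CZ2	
TRP	sidechain	CZ3	
TRP	sidechain	CH2	
TYR	sidechain	CB	
TYR	sidechain	CG	
TYR	sidechain	CD1	
TYR	sidechain	CD2	
TYR	sidechain	CE1	
TYR	sidechain	CE2	
TYR	sidechain	CZ	
TYR	sidechain	OH	
VAL	sidechain	CB	
VAL	sidechain	CG1	
VAL	sidechain	CG2	
PTR	sidechain	CB	
PTR	sidechain	CG	
PTR	sidechain	CD1	
PTR	sidechain	CD2	
PTR	sidechain	CE1	
PTR	sidechain	CE2	
PTR	sidechain	CZ	
PTR	sidechain	OH	
PTR	sidechain	P	
PTR	sidechain	O1P	
PTR	sidechain	O2P	
PTR	sidechain	O3P	
ARG	donor	NE	HE
ARG	donor	NH1	HH11|HH12
ARG	donor	NH2	HH21|HH22
ASN	donor	ND2	HD21|HD22
GLN	donor	NE2	HE21|HE22
HIS	donor	ND1	HD1
HIS	donor	NE2	HE2
LYS	donor	NZ	HZ1|HZ2|HZ3
SER	donor	OG	HG
THR	donor	OG1	HG1
TYR	donor	OH	HH
TRP	donor	NE1	HE1
CYS	donor	SG	HG
ASP	acceptor	OD1	
ASP	acceptor	OD2	
GLU	acceptor	OE1	
GLU	acceptor	OE2	
ASN	acceptor	OD1	
GLN	acceptor	OE1	
SER	acceptor	OG	
THR	acceptor	OG1	
TYR	acceptor	OH	
HIS	acceptor	ND1	
HIS	acceptor	NE2	
MET	acceptor	SD	
CYS	acceptor	SG	
PTR	acceptor	O1P	
PTR	acceptor	O2P	
PTR	acceptor	O3P	
ARG	pos_charge	NE	
ARG	pos_charge	NH1	
ARG	pos_charge	NH2	
ARG	pos_charge	CZ	
LYS	pos_charge	NZ	
ASP	neg_charge	OD1	
ASP	neg_charge	OD2	
ASP	neg_charge	CG	
GLU	neg_charge	OE1	
GLU	neg_charge	OE2	
GLU	neg_charge	CD	
PTR	neg_charge	O1P	
PTR	neg_charge	O2P	
PTR	neg_charge	O3P	
PTR	neg_charge	P	
PHE	aromatic	CG	
TYR	aromatic	CG	
PTR	aromatic	CG	
PHE	aromatic	CD1	
TYR	aromatic	CD1	
PTR	aromatic	CD1	
PHE	aromatic	CD2	
TYR	aromatic	CD2	
PTR	aromatic	CD2	
PHE	aromatic	CE1	
TYR	aromatic	CE1	
PTR	aromatic	CE1	
PHE	aromatic	CE2	
TYR	aromatic	CE2	
PTR	aromatic	CE2	
PHE	aromatic	CZ	
TYR	aromatic	CZ	
PTR	aromatic	CZ	
HIS	aromatic	CG	
HIS	aromatic	ND1	
HIS	aromatic	CD2	
HIS	aromatic	CE1	
HIS	aromatic	NE2	
TRP	aromatic	CG	
TRP	aromatic	CD1	
TRP	aromatic	CD2	
TRP	aromatic	NE1	
TRP	aromatic	CE2	
TRP	aromatic	CE3	
TRP	aromatic	CZ2	
TRP	aromatic	CZ3	
TRP	aromatic	CH2	
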