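# Heavy-atom residue templates in the spirit of MMFF94 bond-charge
# increments (larger amide/carboxylate polarity than the CHARMM-like
# set). Hydrogen charges folded into bonded heavy atoms; per-residue sums
# equal the formal charge.
# Backbone (all residues except Pro): N -0.30, CA 0.27, C 0.60, O -0.57.
residue_name	atom_name	charge
ALA	N	-0.30
ALA	CA	0.27
ALA	C	0.60
ALA	O	-0.57
ALA	CB	0.00
ARG	N	-0.30
ARG	CA	0.27
ARG	C	0.60
ARG	O	-0.57
ARG	CB	0.00
ARG	CG	0.00
ARG	CD	0.40
ARG	NE	-0.20
ARG	CZ	0.60
ARG	NH1	0.10
ARG	NH2	0.10
ASN	N	-0.30
ASN	CA	0.27
ASN	C	0.60
ASN	O	-0.57
ASN	CB	0.00
ASN	CG	0.57
ASN	OD1	-0.57
ASN	ND2	0.00
ASP	N	-0.30
ASP	CA	0.27
ASP	C	0.60
ASP	O	-0.57
ASP	CB	-0.06
ASP	CG	0.66
ASP	OD1	-0.80
ASP	OD2	-0.80
CYS	N	-0.30
CYS	CA	0.27
CYS	C	0.60
CYS	O	-0.57
CYS	CB	0.10
CYS	SG	-0.10
GLN	N	-0.30
GLN	CA	0.27
GLN	C	0.60
GLN	O	-0.57
GLN	CB	0.00
GLN	CG	0.00
GLN	CD	0.57
GLN	OE1	-0.57
GLN	NE2	0.00
GLU	N	-0.30
GLU	CA	0.27
GLU	C	0.60
GLU	O	-0.57
GLU	CB	0.00
GLU	CG	-0.06
GLU	CD	0.66
GLU	OE1	-0.80
GLU	OE2	-0.80
GLY	N	-0.30
GLY	CA	0.27
GLY	C	0.60
GLY	O	-0.57
HIS	N	-0.30
HIS	CA	0.27
HIS	C	0.60
HIS	O	-0.57
HIS	CB	0.10
HIS	CG	-0.10
HIS	ND1	-0.06
HIS	CD2	0.25
HIS	CE1	0.41
HIS	NE2	-0.60
ILE	N	-0.30
ILE	CA	0.27
ILE	C	0.60
ILE	O	-0.57
ILE	CB	0.00
ILE	CG1	0.00
ILE	CG2	0.00
ILE	CD1	0.00
LEU	N	-0.30
LEU	CA	0.27
LEU	C	0.60
LEU	O	-0.57
LEU	CB	0.00
LEU	CG	0.00
LEU	CD1	0.00
LEU	CD2	0.00
LYS	N	-0.30
LYS	CA	0.27
LYS	C	0.60
LYS	O	-0.57
LYS	CB	0.00
LYS	CG	0.00
LYS	CD	0.00
LYS	CE	0.35
LYS	NZ	0.65
MET	N	-0.30
MET	CA	0.27
MET	C	0.60
MET	O	-0.57
MET	CB	0.00
MET	CG	0.06
MET	SD	-0.12
MET	CE	0.06
PHE	N	-0.30
PHE	CA	0.27
PHE	C	0.60
PHE	O	-0.57
PHE	CB	0.00
PHE	CG	0.00
PHE	CD1	0.00
PHE	CD2	0.00
PHE	CE1	0.00
PHE	CE2	0.00
PHE	CZ	0.00
PRO	N	-0.30
PRO	CA	0.27
PRO	C	0.60
PRO	O	-0.57
PRO	CB	0.00
PRO	CG	0.00
PRO	CD	0.00
SER	N	-0.30
SER	CA	0.27
SER	C	0.60
SER	O	-0.57
SER	CB	0.28
SER	OG	-0.28
THR	N	-0.30
THR	CA	0.27
THR	C	0.60
THR	O	-0.57
THR	CB	0.28
THR	OG1	-0.28
THR	CG2	0.00
TRP	N	-0.30
TRP	CA	0.27
TRP	C	0.60
TRP	O	-0.57
TRP	CB	0.00
TRP	CG	0.00
TRP	CD1	0.10
TRP	NE1	-0.18
TRP	CE2	0.08
TRP	CD2	0.00
TRP	CE3	0.00
TRP	CZ2	0.00
TRP	CZ3	0.00
TRP	CH2	0.00
TYR	N	-0.30
TYR	CA	0.27
TYR	C	0.60
TYR	O	-0.57
TYR	CB	0.00
TYR	CG	0.00
TYR	CD1	0.00
TYR	CD2	0.00
TYR	CE1	0.00
TYR	CE2	0.00
TYR	CZ	0.15
TYR	OH	-0.15
VAL	N	-0.30
VAL	CA	0.27
VAL	C	0.60
VAL	O	-0.57
VAL	CB	0.00
VAL	CG1	0.00
VAL	CG2	0.00
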