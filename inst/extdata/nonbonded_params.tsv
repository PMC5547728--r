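res_name	atom_name	epsilon	rmin_half	charge
ALA	N	0.17	1.824	-0.14
ALA	CA	0.1094	1.908	0.05
ALA	C	0.086	1.908	0.6
ALA	O	0.21	1.6612	-0.57
ALA	OXT	0.21	1.6612	-0.8
ALA	CB	0.1094	1.908	0.05
ARG	N	0.17	1.824	-0.14
ARG	CA	0.1094	1.908	0.05
ARG	C	0.086	1.908	0.6
ARG	O	0.21	1.6612	-0.57
ARG	OXT	0.21	1.6612	-0.8
ARG	CB	0.1094	1.908	0.05
ARG	CG	0.1094	1.908	0.05
ARG	CD	0.1094	1.908	0.05
ARG	NE	0.17	1.824	0.55
ARG	CZ	0.086	1.908	0.6
ARG	NH1	0.17	1.824	0.55
ARG	NH2	0.17	1.824	0.55
ASN	N	0.17	1.824	-0.14
ASN	CA	0.1094	1.908	0.05
ASN	C	0.086	1.908	0.6
ASN	O	0.21	1.6612	-0.57
ASN	OXT	0.21	1.6612	-0.8
ASN	CB	0.1094	1.908	0.05
ASN	CG	0.086	1.908	0.6
ASN	OD1	0.21	1.6612	-0.57
ASN	ND2	0.17	1.824	-0.05
ASP	N	0.17	1.824	-0.14
ASP	CA	0.1094	1.908	0.05
ASP	C	0.086	1.908	0.6
ASP	O	0.21	1.6612	-0.57
ASP	OXT	0.21	1.6612	-0.8
ASP	CB	0.1094	1.908	0.05
ASP	CG	0.086	1.908	0.6
ASP	OD1	0.21	1.6612	-0.8
ASP	OD2	0.21	1.6612	-0.8
CYS	N	0.17	1.824	-0.14
CYS	CA	0.1094	1.908	0.05
CYS	C	0.086	1.908	0.6
CYS	O	0.21	1.6612	-0.57
CYS	OXT	0.21	1.6612	-0.8
CYS	CB	0.1094	1.908	0.05
CYS	SG	0.25	2	0
GLN	N	0.17	1.824	-0.14
GLN	CA	0.1094	1.908	0.05
GLN	C	0.086	1.908	0.6
GLN	O	0.21	1.6612	-0.57
GLN	OXT	0.21	1.6612	-0.8
GLN	CB	0.1094	1.908	0.05
GLN	CG	0.1094	1.908	0.05
GLN	CD	0.086	1.908	0.6
GLN	OE1	0.21	1.6612	-0.57
GLN	NE2	0.17	1.824	-0.05
GLU	N	0.17	1.824	-0.14
GLU	CA	0.1094	1.908	0.05
GLU	C	0.086	1.908	0.6
GLU	O	0.21	1.6612	-0.57
GLU	OXT	0.21	1.6612	-0.8
GLU	CB	0.1094	1.908	0.05
GLU	CG	0.1094	1.908	0.05
GLU	CD	0.086	1.908	0.6
GLU	OE1	0.21	1.6612	-0.8
GLU	OE2	0.21	1.6612	-0.8
GLY	N	0.17	1.824	-0.14
GLY	CA	0.1094	1.908	0.05
GLY	C	0.086	1.908	0.6
GLY	O	0.21	1.6612	-0.57
GLY	OXT	0.21	1.6612	-0.8
HIS	N	0.17	1.824	-0.14
HIS	CA	0.1094	1.908	0.05
HIS	C	0.086	1.908	0.6
HIS	O	0.21	1.6612	-0.57
HIS	OXT	0.21	1.6612	-0.8
HIS	CB	0.1094	1.908	0.05
HIS	CG	0.086	1.908	0
HIS	ND1	0.17	1.824	-0.1
HIS	CD2	0.086	1.908	0
HIS	CE1	0.086	1.908	0
HIS	NE2	0.17	1.824	-0.5
ILE	N	0.17	1.824	-0.14
ILE	CA	0.1094	1.908	0.05
ILE	C	0.086	1.908	0.6
ILE	O	0.21	1.6612	-0.57
ILE	OXT	0.21	1.6612	-0.8
ILE	CB	0.1094	1.908	0.05
ILE	CG1	0.1094	1.908	0.05
ILE	CG2	0.1094	1.908	0.05
ILE	CD1	0.1094	1.908	0.05
LEU	N	0.17	1.824	-0.14
LEU	CA	0.1094	1.908	0.05
LEU	C	0.086	1.908	0.6
LEU	O	0.21	1.6612	-0.57
LEU	OXT	0.21	1.6612	-0.8
LEU	CB	0.1094	1.908	0.05
LEU	CG	0.1094	1.908	0.05
LEU	CD1	0.1094	1.908	0.05
LEU	CD2	0.1094	1.908	0.05
LYS	N	0.17	1.824	-0.14
LYS	CA	0.1094	1.908	0.05
LYS	C	0.086	1.908	0.6
LYS	O	0.21	1.6612	-0.57
LYS	OXT	0.21	1.6612	-0.8
LYS	CB	0.1094	1.908	0.05
LYS	CG	0.1094	1.908	0.05
LYS	CD	0.1094	1.908	0.05
LYS	CE	0.1094	1.908	0.05
LYS	NZ	0.17	1.824	0.55
MET	N	0.17	1.824	-0.14
MET	CA	0.1094	1.908	0.05
MET	C	0.086	1.908	0.6
MET	O	0.21	1.6612	-0.57
MET	OXT	0.21	1.6612	-0.8
MET	CB	0.1094	1.908	0.05
MET	CG	0.1094	1.908	0.05
MET	SD	0.25	2	0
MET	CE	0.1094	1.908	0.05
PHE	N	0.17	1.824	-0.14
PHE	CA	0.1094	1.908	0.05
PHE	C	0.086	1.908	0.6
PHE	O	0.21	1.6612	-0.57
PHE	OXT	0.21	1.6612	-0.8
PHE	CB	0.1094	1.908	0.05
PHE	CG	0.086	1.908	0
PHE	CD1	0.086	1.908	0
PHE	CD2	0.086	1.908	0
PHE	CE1	0.086	1.908	0
PHE	CE2	0.086	1.908	0
PHE	CZ	0.086	1.908	0
PRO	N	0.17	1.824	-0.14
PRO	CA	0.1094	1.908	0.05
PRO	C	0.086	1.908	0.6
PRO	O	0.21	1.6612	-0.57
PRO	OXT	0.21	1.6612	-0.8
PRO	CB	0.1094	1.908	0.05
PRO	CG	0.1094	1.908	0.05
PRO	CD	0.1094	1.908	0.05
SER	N	0.17	1.824	-0.14
SER	CA	0.1094	1.908	0.05
SER	C	0.086	1.908	0.6
SER	O	0.21	1.6612	-0.57
SER	OXT	0.21	1.6612	-0.8
SER	CB	0.1094	1.908	0.05
SER	OG	0.2104	1.721	-0.21
THR	N	0.17	1.824	-0.14
THR	CA	0.1094	1.908	0.05
THR	C	0.086	1.908	0.6
THR	O	0.21	1.6612	-0.57
THR	OXT	0.21	1.6612	-0.8
THR	CB	0.1094	1.908	0.05
THR	OG1	0.2104	1.721	-0.21
THR	CG2	0.1094	1.908	0.05
TRP	N	0.17	1.824	-0.14
TRP	CA	0.1094	1.908	0.05
TRP	C	0.086	1.908	0.6
TRP	O	0.21	1.6612	-0.57
TRP	OXT	0.21	1.6612	-0.8
TRP	CB	0.1094	1.908	0.05
TRP	CG	0.086	1.908	0
TRP	CD1	0.086	1.908	0
TRP	CD2	0.086	1.908	0
TRP	NE1	0.17	1.824	-0.1
TRP	CE2	0.086	1.908	0
TRP	CE3	0.086	1.908	0
TRP	CZ2	0.086	1.908	0
TRP	CZ3	0.086	1.908	0
TRP	CH2	0.086	1.908	0
TYR	N	0.17	1.824	-0.14
TYR	CA	0.1094	1.908	0.05
TYR	C	0.086	1.908	0.6
TYR	O	0.21	1.6612	-0.57
TYR	OXT	0.21	1.6612	-0.8
TYR	CB	0.1094	1.908	0.05
TYR	CG	0.086	1.908	0
TYR	CD1	0.086	1.908	0
TYR	CD2	0.086	1.908	0
TYR	CE1	0.086	1.908	0
TYR	CE2	0.086	1.908	0
TYR	CZ	0.086	1.908	0
TYR	OH	0.2104	1.721	-0.21
VAL	N	0.17	1.824	-0.14
VAL	CA	0.1094	1.908	0.05
VAL	C	0.086	1.908	0.6
VAL	O	0.21	1.6612	-0.57
VAL	OXT	0.21	1.6612	-0.8
VAL	CB	0.1094	1.908	0.05
VAL	CG1	0.1094	1.908	0.05
VAL	CG2	0.1094	1.908	0.05
AMP	N1	0.17	1.824	-0.5
AMP	C2	0.086	1.908	0
AMP	N3	0.17	1.824	-0.5
AMP	C4	0.086	1.908	0
AMP	C5	0.086	1.908	0
AMP	C6	0.086	1.908	0
AMP	N6	0.17	1.824	-0.05
AMP	N7	0.17	1.824	-0.5
AMP	C8	0.086	1.908	0
AMP	N9	0.17	1.824	-0.5
AMP	C1'	0.1094	1.908	0.05
AMP	C2'	0.1094	1.908	0.05
AMP	O2'	0.2104	1.721	-0.21
AMP	C3'	0.1094	1.908	0.05
AMP	O3'	0.2104	1.721	-0.21
AMP	C4'	0.1094	1.908	0.05
AMP	O4'	0.17	1.6837	-0.4
AMP	C5'	0.1094	1.908	0.05
AMP	O5'	0.17	1.6837	-0.4
AMP	PA	0.2	2.1	1.2
AMP	O1A	0.21	1.6612	-0.9
AMP	O2A	0.21	1.6612	-0.9
AMP	O3A	0.21	1.6612	-0.9
ADP	N1	0.17	1.824	-0.5
ADP	C2	0.086	1.908	0
ADP	N3	0.17	1.824	-0.5
ADP	C4	0.086	1.908	0
ADP	C5	0.086	1.908	0
ADP	C6	0.086	1.908	0
ADP	N6	0.17	1.824	-0.05
ADP	N7	0.17	1.824	-0.5
ADP	C8	0.086	1.908	0
ADP	N9	0.17	1.824	-0.5
ADP	C1'	0.1094	1.908	0.05
ADP	C2'	0.1094	1.908	0.05
ADP	O2'	0.2104	1.721	-0.21
ADP	C3'	0.1094	1.908	0.05
ADP	O3'	0.2104	1.721	-0.21
ADP	C4'	0.1094	1.908	0.05
ADP	O4'	0.17	1.6837	-0.4
ADP	C5'	0.1094	1.908	0.05
ADP	O5'	0.17	1.6837	-0.4
ADP	PA	0.2	2.1	1.2
ADP	O1A	0.21	1.6612	-0.9
ADP	O2A	0.21	1.6612	-0.9
ADP	O3A	0.17	1.6837	-0.4
ADP	PB	0.2	2.1	1.2
ADP	O1B	0.21	1.6612	-0.9
ADP	O2B	0.21	1.6612	-0.9
ADP	O3B	0.21	1.6612	-0.9
ATP	N1	0.17	1.824	-0.5
ATP	C2	0.086	1.908	0
ATP	N3	0.17	1.824	-0.5
ATP	C4	0.086	1.908	0
ATP	C5	0.086	1.908	0
ATP	C6	0.086	1.908	0
ATP	N6	0.17	1.824	-0.05
ATP	N7	0.17	1.824	-0.5
ATP	C8	0.086	1.908	0
ATP	N9	0.17	1.824	-0.5
ATP	C1'	0.1094	1.908	0.05
ATP	C2'	0.1094	1.908	0.05
ATP	O2'	0.2104	1.721	-0.21
ATP	C3'	0.1094	1.908	0.05
ATP	O3'	0.2104	1.721	-0.21
ATP	C4'	0.1094	1.908	0.05
ATP	O4'	0.17	1.6837	-0.4
ATP	C5'	0.1094	1.908	0.05
ATP	O5'	0.17	1.6837	-0.4
ATP	PA	0.2	2.1	1.2
ATP	O1A	0.21	1.6612	-0.9
ATP	O2A	0.21	1.6612	-0.9
ATP	O3A	0.17	1.6837	-0.4
ATP	PB	0.2	2.1	1.2
ATP	O1B	0.21	1.6612	-0.9
ATP	O2B	0.21	1.6612	-0.9
ATP	O3B	0.17	1.6837	-0.4
ATP	PG	0.2	2.1	1.2
ATP	O1G	0.21	1.6612	-0.9
ATP	O2G	0.21	1.6612	-0.9
ATP	O3G	0.21	1.6612	-0.9
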