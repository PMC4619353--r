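# Formal charge model: unit charges on charged sidechain termini only.
# Arg/Lys +1 distributed on terminal N atoms; Asp/Glu -1 on carboxylate O.
# All atoms not listed here carry the model default (0 e).
residue_name	atom_name	charge
ARG	NH1	0.5
ARG	NH2	0.5
LYS	NZ	1.0
ASP	OD1	-0.5
ASP	OD2	-0.5
GLU	OE1	-0.5
GLU	OE2	-0.5
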