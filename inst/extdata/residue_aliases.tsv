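# Residue-name and atom-name alias table (editable data).
# kind=residue rows map residue names to (base_type, variant);
# kind=atom rows map atom-name synonyms to canonical primed names.
# Variant vocabulary: deoxy, ribo, 2F-ribo, 2F-arabino, LNA, unknown.
# 2'-modified guanosine codes follow common component-naming conventions but
# are NOT validated against the live PDB chemical component dictionary;
# extend this table for entry-specific codes.
kind	from	to	base_type	variant
residue	DG	-	G	deoxy
residue	GUA	-	G	deoxy
residue	G	-	G	ribo
residue	RG	-	G	ribo
residue	GF2	-	G	2F-ribo
residue	2FG	-	G	2F-ribo
residue	GFL	-	G	2F-ribo
residue	GFA	-	G	2F-arabino
residue	FAG	-	G	2F-arabino
residue	LNG	-	G	LNA
residue	GLN	-	G	LNA
residue	DA	-	A	deoxy
residue	ADE	-	A	deoxy
residue	A	-	A	ribo
residue	RA	-	A	ribo
residue	DC	-	C	deoxy
residue	CYT	-	C	deoxy
residue	C	-	C	ribo
residue	RC	-	C	ribo
residue	DT	-	T	deoxy
residue	THY	-	T	deoxy
residue	T	-	T	deoxy
residue	DU	-	U	deoxy
residue	U	-	U	ribo
residue	RU	-	U	ribo
atom	O1'	O4'	-	-
atom	C5M	C7	-	-
atom	O3T	O3'	-	-
atom	O5T	O5'	-	-
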